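# Readers and writers for the external formats the pipeline touches:
# MDL molfiles (V2000), annotation tables, pathway hierarchy relations,
# and feature matrices.  Only the V2000 connection-table dialect is handled;
# V3000 input is rejected explicitly.

.chg_code_to_charge <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L,
                         "4" = 0L, "5" = -1L, "6" = -2L, "7" = -3L)

.substr_int <- function(x, from, to) {
  suppressWarnings(as.integer(trimws(substr(x, from, to))))
}

#' Parse an MDL V2000 molfile
#'
#' Reads the counts line, atom block, bond block, and `M  CHG` property
#' lines of a V2000 connection table.  Formal charges are taken from the
#' atom-block charge column; if any `M  CHG` property line is present it
#' supersedes all atom-block charges (the modern MDL convention).
#'
#' @param text A single string holding the molfile contents.
#' @param compound_id Identifier to assign; defaults to the trimmed title
#'   line, or `"unnamed"` when the title is blank.
#' @return A [molecule_graph()].
#' @export
parse_molfile <- function(text, compound_id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- sub("\r$", "", strsplit(text, "\n", fixed = TRUE)[[1L]])
  if (length(lines) < 4L) {
    stop("molfile format error: fewer than 4 lines (header + counts line)",
         call. = FALSE)
  }
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop("V3000 molfiles are not supported: only the V2000 connection-table ",
         "dialect is read", call. = FALSE)
  }
  natoms <- .substr_int(counts, 1L, 3L)
  nbonds <- .substr_int(counts, 4L, 6L)
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L) {
    stop("molfile format error: malformed counts line: ",
         dQuote(counts), call. = FALSE)
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("molfile format error: atom/bond block truncated", call. = FALSE)
  }

  elements <- character(natoms)
  charges <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    if (nchar(ln) >= 34L) {
      elements[i] <- trimws(substr(ln, 32L, 34L))
      code <- trimws(substr(ln, 37L, 39L))
    } else {
      # tolerate whitespace-separated atom lines (minimal hand-written files)
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      if (length(tok) < 4L) {
        stop("molfile format error: unparseable atom line: ", dQuote(ln),
             call. = FALSE)
      }
      elements[i] <- tok[4L]
      code <- if (length(tok) >= 6L) tok[6L] else "0"
    }
    if (!nzchar(code)) code <- "0"
    chg <- .chg_code_to_charge[code]
    charges[i] <- if (is.na(chg)) 0L else chg
  }

  bonds <- matrix(integer(0), 0L, 3L)
  if (nbonds > 0L) {
    bonds <- matrix(0L, nbonds, 3L)
    for (j in seq_len(nbonds)) {
      ln <- lines[4L + natoms + j]
      a <- .substr_int(ln, 1L, 3L)
      b <- .substr_int(ln, 4L, 6L)
      o <- .substr_int(ln, 7L, 9L)
      if (anyNA(c(a, b, o))) {
        tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
        if (length(tok) < 3L) {
          stop("molfile format error: unparseable bond line: ", dQuote(ln),
               call. = FALSE)
        }
        a <- suppressWarnings(as.integer(tok[1L]))
        b <- suppressWarnings(as.integer(tok[2L]))
        o <- suppressWarnings(as.integer(tok[3L]))
      }
      if (anyNA(c(a, b, o))) {
        stop("molfile format error: unparseable bond line: ", dQuote(ln),
             call. = FALSE)
      }
      if (a < 1L || a > natoms || b < 1L || b > natoms) {
        stop("molfile index error: bond ", j, " references atom outside 1..",
             natoms, call. = FALSE)
      }
      bonds[j, ] <- c(a, b, o)
    }
  }

  # M  CHG property lines supersede the whole atom-block charge column.
  prop <- lines[-seq_len(4L + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", prop, value = TRUE)
  if (length(chg_lines)) {
    charges <- integer(natoms)
    for (ln in chg_lines) {
      tok <- strsplit(trimws(substring(ln, 7L)), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.integer(tok))
      if (anyNA(vals) || length(vals) < 3L || length(vals) %% 2L != 1L) {
        stop("molfile format error: malformed M  CHG line: ", dQuote(ln),
             call. = FALSE)
      }
      pairs <- matrix(vals[-1L], ncol = 2L, byrow = TRUE)
      if (any(pairs[, 1L] < 1L | pairs[, 1L] > natoms)) {
        stop("molfile index error: M  CHG references atom outside 1..",
             natoms, call. = FALSE)
      }
      charges[pairs[, 1L]] <- pairs[, 2L]
    }
  }

  if (is.null(compound_id)) {
    compound_id <- trimws(lines[1L])
    if (!nzchar(compound_id)) compound_id <- "unnamed"
  }
  molecule_graph(compound_id, elements, charges, bonds)
}

#' Write a molecular graph as an MDL V2000 molfile
#'
#' The title line carries the compound ID; coordinates are written as zeros
#' (the featurization is purely topological).  Nonzero formal charges are
#' serialized as `M  CHG` property lines, which is also how [parse_molfile()]
#' reads them back, so write/parse round trips are exact.
#'
#' @param graph A [molecule_graph()].
#' @return A single string (with trailing newline) in V2000 format.
#' @export
write_molfile <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  n <- length(graph$elements)
  nb <- nrow(graph$bonds)
  if (n > 999L || nb > 999L) {
    stop("V2000 capacity error: at most 999 atoms/bonds ",
         "(3-character count fields)", call. = FALSE)
  }
  out <- c(graph$compound_id, "  pathcolor", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  out <- c(out, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, graph$elements))
  if (nb) {
    out <- c(out, sprintf("%3d%3d%3d  0", graph$bonds[, 1L],
                          graph$bonds[, 2L], graph$bonds[, 3L]))
  }
  chg <- which(graph$charges != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
      out <- c(out, paste0(sprintf("M  CHG%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp,
                                          graph$charges[grp]),
                                  collapse = "")))
    }
  }
  paste0(paste(c(out, "M  END"), collapse = "\n"), "\n")
}

#' Read a compound-to-pathway annotation table
#'
#' Two dialects are supported.  `"two_column"` expects rows of
#' `pathway<TAB>compound` (comma also accepted as separator).
#' `"reactome_chebi"` expects the tab-separated Reactome ChEBI mapping layout
#' (compound ID, pathway stable ID, URL, event name, evidence code, species);
#' compound IDs gain a `"CHEBI:"` prefix when it is absent.  Rows with a
#' missing ID are skipped with a message; duplicate pairs are collapsed.
#'
#' @param path File path (or connection) to read.
#' @param dialect `"two_column"` or `"reactome_chebi"`.
#' @param species Optional character vector: in the `reactome_chebi` dialect,
#'   keep only rows whose species column matches.  Default keeps all species.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, dialect = c("two_column", "reactome_chebi"),
                             species = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "two_column") {
    sep <- if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ","
    fields <- strsplit(lines, sep, fixed = TRUE)
    pw <- trimws(vapply(fields, function(f) if (length(f) >= 1L) f[1L] else "",
                        character(1L)))
    cp <- trimws(vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "",
                        character(1L)))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    cp <- trimws(vapply(fields, function(f) if (length(f) >= 1L) f[1L] else "",
                        character(1L)))
    pw <- trimws(vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "",
                        character(1L)))
    sp <- trimws(vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "",
                        character(1L)))
    has_prefix <- grepl("^CHEBI:", cp)
    cp[!has_prefix & nzchar(cp)] <- paste0("CHEBI:", cp[!has_prefix & nzchar(cp)])
    if (!is.null(species)) {
      keep <- sp %in% species
      cp <- cp[keep]; pw <- pw[keep]
    }
  }
  ok <- nzchar(cp) & nzchar(pw)
  if (sum(!ok)) {
    message("read_annotations: skipped ", sum(!ok),
            " row(s) with missing IDs")
  }
  cp <- cp[ok]; pw <- pw[ok]
  if (!length(cp)) stop("read_annotations: no usable rows", call. = FALSE)
  annotation_table(cp, pw)
}

#' Construct an annotation table
#'
#' Holds the set of (compound, pathway) membership pairs; duplicates are
#' collapsed.  An empty table is permitted (downstream steps that need
#' positives raise their own errors).
#'
#' @param compound_id,pathway_id Character vectors of equal length.
#' @return A data frame of class `annotation_table` with columns
#'   `compound_id` and `pathway_id`.
#' @export
annotation_table <- function(compound_id = character(0),
                             pathway_id = character(0)) {
  compound_id <- as.character(compound_id)
  pathway_id <- as.character(pathway_id)
  stopifnot(length(compound_id) == length(pathway_id))
  if (anyNA(compound_id) || anyNA(pathway_id) ||
      any(!nzchar(compound_id)) || any(!nzchar(pathway_id))) {
    stop("annotation IDs must be non-empty strings", call. = FALSE)
  }
  keep <- !duplicated(paste(compound_id, pathway_id, sep = "\r"))
  structure(data.frame(compound_id = compound_id[keep],
                       pathway_id = pathway_id[keep],
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Read a pathway hierarchy relation file
#'
#' Expects `parent<TAB>child` rows (comma also accepted).  The edge set is
#' validated to be acyclic; a detected cycle aborts with one offending edge
#' named.
#'
#' @param path File path (or connection).
#' @return A [pathway_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_hierarchy: empty input", call. = FALSE)
  sep <- if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  parent <- trimws(vapply(fields, `[`, character(1L), 1L))
  child <- trimws(vapply(fields, function(f)
    if (length(f) >= 2L) f[2L] else "", character(1L)))
  ok <- nzchar(parent) & nzchar(child)
  if (!all(ok)) {
    message("read_hierarchy: skipped ", sum(!ok), " malformed row(s)")
  }
  pathway_hierarchy(parent[ok], child[ok])
}

#' Construct a pathway hierarchy
#'
#' A set of directed parent-to-child edges over pathway IDs.  Self-edges are
#' rejected and the directed graph must be acyclic.
#'
#' @param parent,child Character vectors of equal length.
#' @return An object of class `pathway_hierarchy` with an `edges` data frame.
#' @export
pathway_hierarchy <- function(parent = character(0), child = character(0)) {
  parent <- as.character(parent); child <- as.character(child)
  stopifnot(length(parent) == length(child))
  if (any(parent == child)) {
    stop("hierarchy error: self-edge ", parent[which(parent == child)[1L]],
         " -> itself", call. = FALSE)
  }
  keep <- !duplicated(paste(parent, child, sep = "\r"))
  parent <- parent[keep]; child <- child[keep]
  # Kahn's algorithm; leftover edges after peeling indicate a cycle.
  nodes <- union(parent, child)
  indeg <- table(factor(child, levels = nodes))
  active <- rep(TRUE, length(parent))
  queue <- nodes[indeg == 0L]
  indeg <- as.integer(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- which(active & parent == v)
    for (e in out) {
      active[e] <- FALSE
      w <- child[e]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (any(active)) {
    e <- which(active)[1L]
    stop("hierarchy error: cycle detected involving edge ",
         parent[e], " -> ", child[e], call. = FALSE)
  }
  structure(list(edges = data.frame(parent = parent, child = child,
                                    stringsAsFactors = FALSE)),
            class = "pathway_hierarchy")
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat(sprintf("<pathway_hierarchy> %d edges, %d pathways\n",
              nrow(x$edges), length(union(x$edges$parent, x$edges$child))))
  invisible(x)
}

#' Save or load a feature matrix as tab-separated text
#'
#' The on-disk layout is one header comment recording whether the matrix is
#' normalized, a column-name row (`entity_id` followed by the vocabulary in
#' order), then one row per entity.  Values are written with 17 significant
#' digits so the round trip is lossless for counts and for normalized values
#' alike.
#'
#' @param matrix A [feature_matrix()].
#' @param path Destination file.
#' @param vocabulary Optional character vector: when supplied to
#'   `load_matrix()`, the stored vocabulary must match it exactly
#'   (schema check for appending workflows).
#' @return `save_matrix()` returns `path` invisibly; `load_matrix()` returns
#'   a [feature_matrix()].
#' @export
save_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  header <- paste(c("entity_id", colnames(v)), collapse = "\t")
  rows <- character(nrow(v))
  if (nrow(v)) {
    txt <- formatC(v, digits = 17L, format = "g", width = 1L)
    rows <- paste(rownames(v), apply(txt, 1L, paste, collapse = "\t"),
                  sep = if (ncol(v)) "\t" else "")
  }
  writeLines(c(sprintf("#pathcolor_matrix normalized=%s",
                       matrix$normalized), header, rows), path)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path, vocabulary = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "#pathcolor_matrix")) {
    stop("not a pathcolor feature-matrix file: ", path, call. = FALSE)
  }
  normalized <- grepl("normalized=TRUE", lines[1L], fixed = TRUE)
  cols <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (cols[1L] != "entity_id") {
    stop("feature-matrix schema error: missing entity_id column", call. = FALSE)
  }
  vocab <- cols[-1L]
  if (!is.null(vocabulary) && !identical(vocab, as.character(vocabulary))) {
    stop("feature-matrix schema error: stored vocabulary does not match ",
         "the expected vocabulary", call. = FALSE)
  }
  body <- lines[-(1:2)]
  n <- length(body)
  vals <- base::matrix(0, n, length(vocab))
  ids <- character(n)
  if (n) {
    sp <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(sp, `[`, character(1L), 1L)
    if (length(vocab)) {
      vals <- do.call(rbind, lapply(sp, function(f) as.numeric(f[-1L])))
    }
  }
  rownames(vals) <- ids
  colnames(vals) <- vocab
  feature_matrix(vals, normalized = normalized)
}
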