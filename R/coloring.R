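# Iterative neighborhood atom coloring: every atom receives a canonical
# string label describing its rooted neighborhood up to a radius, in the
# spirit of Weisfeiler-Lehman refinement / circular substructure counting.
# Counting label occurrences over a corpus yields substructure-count
# feature vectors.
#
# Color grammar (version "pc1"):
#   radius 0:  elem, with the formal charge appended when nonzero ("N+1")
#   radius r+1: prev "|" then "(order:neighbor_prev)" tokens sorted
#               lexicographically (C collation), concatenated
# Two atoms in any graphs share a color at radius r exactly when their
# depth-r rooted neighborhoods are isomorphic under this encoding; the
# encoding is invariant to atom input order by construction (sorted tokens).

.color_grammar_version <- "pc1"

#' Remove hydrogens from a molecular graph
#'
#' Drops all H atoms and their incident bonds; the remaining atoms are
#' re-indexed preserving their original order.  An all-hydrogen molecule
#' yields an empty graph.
#'
#' @param graph A [molecule_graph()].
#' @return A hydrogen-free [molecule_graph()].
#' @export
strip_hydrogens <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  keep <- graph$elements != "H"
  if (all(keep)) return(graph)
  new_idx <- cumsum(keep)
  b <- graph$bonds
  if (nrow(b)) {
    kb <- keep[b[, 1L]] & keep[b[, 2L]]
    b <- b[kb, , drop = FALSE]
    b[, 1L] <- new_idx[b[, 1L]]
    b[, 2L] <- new_idx[b[, 2L]]
  }
  molecule_graph(graph$compound_id, graph$elements[keep],
                 graph$charges[keep], b)
}

#' Compound size: number of non-hydrogen atoms
#'
#' @param graph A [molecule_graph()].
#' @return Integer count of heavy atoms.
#' @export
compound_size <- function(graph) {
  stopifnot(inherits(graph, "molecule_graph"))
  sum(graph$elements != "H")
}

# Longest shortest path over all connected components (graph diameter),
# by BFS from every atom.  Tiny graphs only, so O(n * m) is fine.
.graph_diameter <- function(graph) {
  n <- length(graph$elements)
  if (n == 0L || nrow(graph$bonds) == 0L) return(0L)
  adj <- .mol_adjacency(graph)
  diam <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]][, 1L]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    diam <- max(diam, max(dist, na.rm = TRUE))
  }
  diam
}

#' Compute per-atom neighborhood colors at radii 0..R
#'
#' Radius-0 colors are the element symbol, suffixed with the formal charge
#' when nonzero.  Each subsequent radius extends an atom's color with the
#' lexicographically sorted multiset of `(bond order : neighbor color)`
#' tokens, so equal colors mean isomorphic rooted neighborhoods and the
#' result is invariant to atom input order.  The graph is expected to be
#' hydrogen-stripped (see [strip_hydrogens()]).
#'
#' @param graph A [molecule_graph()].
#' @param max_radius A non-negative integer, or `"auto"`: refine until the
#'   number of distinct colors in the graph stops increasing, capped at the
#'   graph diameter.
#' @return A list with one character vector per radius (`[[1]]` = radius 0),
#'   each of length `n_atoms`; an empty list for an empty graph.
#' @export
color_atoms <- function(graph, max_radius = 2L) {
  stopifnot(inherits(graph, "molecule_graph"))
  n <- length(graph$elements)
  if (n == 0L) return(list())
  auto <- identical(max_radius, "auto")
  if (!auto) {
    max_radius <- as.integer(max_radius)
    stopifnot(length(max_radius) == 1L, !is.na(max_radius), max_radius >= 0L)
  }
  cap <- if (auto) .graph_diameter(graph) else max_radius

  chg <- graph$charges
  col0 <- ifelse(chg == 0L, graph$elements,
                 paste0(graph$elements, ifelse(chg > 0L, "+", "-"), abs(chg)))
  out <- list(col0)
  if (cap == 0L) return(out)
  adj <- .mol_adjacency(graph)
  prev <- col0
  for (r in seq_len(cap)) {
    cur <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (nrow(nb) == 0L) {
        cur[i] <- prev[i]
      } else {
        tok <- paste0("(", nb[, 2L], ":", prev[nb[, 1L]], ")")
        cur[i] <- paste0(prev[i], "|",
                         paste(sort(tok, method = "radix"), collapse = ""))
      }
    }
    if (auto && length(unique(cur)) == length(unique(prev))) break
    out[[r + 1L]] <- cur
    prev <- cur
  }
  out
}

#' Count substructure occurrences (color multiplicities) in one compound
#'
#' Takes the union of colors over all radii; the count of a color is the
#' number of atoms bearing it at the radius where it (first) occurs.  Atoms
#' without neighbors keep the same color at every radius and are counted
#' once.
#'
#' @inheritParams color_atoms
#' @return A named non-negative integer vector, names being color strings.
#' @export
color_counts <- function(graph, max_radius = 2L) {
  cols <- color_atoms(graph, max_radius)
  out <- integer(0)
  for (vec in cols) {
    tab <- table(vec)
    new <- setdiff(names(tab), names(out))
    if (length(new)) {
      add <- as.integer(tab[new])
      names(add) <- new
      out <- c(out, add)
    }
  }
  out
}

#' Construct a feature matrix
#'
#' Entity-by-color matrix of substructure counts (raw) or column-scaled
#' values (normalized).  Row names are the entity IDs, column names the
#' color vocabulary in its fixed order.
#'
#' @param values Numeric matrix with row and column names.
#' @param normalized Logical flag; raw matrices hold non-negative integer
#'   counts, normalized matrices hold values in `[0, 1]`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, normalized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values) || ncol(values) == 0L)
  storage.mode(values) <- "double"
  if (nrow(values) && is.null(rownames(values))) {
    stop("feature_matrix requires row names (entity IDs)", call. = FALSE)
  }
  if (ncol(values) && is.null(colnames(values))) {
    stop("feature_matrix requires column names (color vocabulary)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate entity IDs in feature matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate colors in vocabulary", call. = FALSE)
  }
  if (length(values) && min(values) < 0) {
    stop("feature values must be non-negative", call. = FALSE)
  }
  if (normalized && length(values) && max(values) > 1) {
    stop("normalized feature values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values, normalized = isTRUE(normalized),
                 grammar = .color_grammar_version),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d entities x %d colors (%s, grammar %s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts", x$grammar))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Entity IDs and color vocabulary of a feature matrix
#' @param x A [feature_matrix()].
#' @return Character vector of row IDs (`entity_ids`) or ordered colors
#'   (`vocabulary`).
#' @export
entity_ids <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  rownames(x$values)
}

#' @rdname entity_ids
#' @export
vocabulary <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  colnames(x$values)
}

#' Featurize a corpus of compounds into a raw count matrix
#'
#' Hydrogens are stripped, each compound's color counts are computed up to
#' `max_radius`, and the vocabulary is the lexicographically sorted union of
#' all colors observed in the corpus.  Rows are ordered by sorted compound
#' ID, so the result depends only on the corpus content, not input order.
#'
#' @param graphs A list of [molecule_graph()] objects with distinct IDs.
#' @param max_radius Radius passed to [color_counts()] (integer or `"auto"`).
#' @return A raw-count [feature_matrix()] over the compounds.
#' @export
featurize_compounds <- function(graphs, max_radius = 2L) {
  if (!length(graphs)) {
    stop("featurize_compounds: empty corpus", call. = FALSE)
  }
  stopifnot(all(vapply(graphs, inherits, logical(1L), "molecule_graph")))
  ids <- vapply(graphs, `[[`, character(1L), "compound_id")
  if (anyDuplicated(ids)) {
    stop("featurize_compounds: duplicate compound IDs", call. = FALSE)
  }
  counts <- lapply(graphs, function(g)
    color_counts(strip_hydrogens(g), max_radius))
  vocab <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)),
                method = "radix")
  ord <- order(ids, method = "radix")
  vals <- matrix(0, length(graphs), length(vocab),
                 dimnames = list(ids[ord], vocab))
  for (k in seq_along(ord)) {
    ct <- counts[[ord[k]]]
    if (length(ct)) vals[k, names(ct)] <- as.numeric(ct)
  }
  feature_matrix(vals, normalized = FALSE)
}
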