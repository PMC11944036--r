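# Building the labeled compound x pathway cross-join dataset: pathway
# feature aggregation, duplicate-row removal, column normalization,
# hierarchy-level assignment, and level-based subsetting.
#
# Fixed order of operations: featurize -> aggregate -> deduplicate ->
# normalize -> cross-join.  Deduplication operates on raw count vectors
# (scaling cannot split ties, only create new ones).

#' Aggregate compound features into pathway feature vectors
#'
#' Each pathway's row is the element-wise sum of the raw count rows of its
#' member compounds.  Annotation pairs whose compound is absent from the
#' matrix are dropped with a message; pathways left with no members are
#' excluded (not emitted as zero rows).
#'
#' @param compound_matrix Raw-count [feature_matrix()] over compounds.
#' @param annotations An [annotation_table()].
#' @return A raw-count [feature_matrix()] over pathways, rows sorted by
#'   pathway ID.
#' @export
aggregate_pathway_features <- function(compound_matrix, annotations) {
  stopifnot(inherits(compound_matrix, "feature_matrix"),
            inherits(annotations, "annotation_table"))
  if (compound_matrix$normalized) {
    stop("aggregate_pathway_features expects raw counts", call. = FALSE)
  }
  present <- annotations$compound_id %in% entity_ids(compound_matrix)
  if (any(!present)) {
    message("aggregate_pathway_features: dropped ", sum(!present),
            " annotation pair(s) whose compound has no feature row")
  }
  ann <- annotations[present, , drop = FALSE]
  if (!nrow(ann)) {
    stop("aggregate_pathway_features: no pathway retains members",
         call. = FALSE)
  }
  rows <- compound_matrix$values[ann$compound_id, , drop = FALSE]
  agg <- rowsum(rows, group = ann$pathway_id, reorder = FALSE)
  agg <- agg[order(rownames(agg), method = "radix"), , drop = FALSE]
  feature_matrix(agg, normalized = FALSE)
}

#' Pathway sizes: summed member-compound sizes
#'
#' The size of a pathway is the sum of the sizes (heavy-atom counts) of all
#' compounds annotated to it.  Pathways with no sized member are excluded
#' rather than reported as zero, consistent with the member-drop rule of
#' [aggregate_pathway_features()].
#'
#' @param annotations An [annotation_table()].
#' @param sizes Named integer vector, compound ID -> heavy-atom count
#'   (see [compound_size()]).
#' @return Named integer vector, pathway ID -> size, sorted by pathway ID.
#' @export
pathway_size <- function(annotations, sizes) {
  stopifnot(inherits(annotations, "annotation_table"))
  ann <- annotations[annotations$compound_id %in% names(sizes), ,
                     drop = FALSE]
  if (!nrow(ann)) return(stats::setNames(integer(0), character(0)))
  out <- tapply(sizes[ann$compound_id], ann$pathway_id, sum)
  out <- out[order(names(out), method = "radix")]
  stats::setNames(as.integer(out), names(out))
}

#' Remove duplicate feature rows, merging their annotations
#'
#' Among rows with identical feature vectors, the lexicographically smallest
#' entity ID is kept as the representative; annotations of removed rows are
#' re-pointed to it (set union).  Intended to run on raw count matrices
#' before normalization.
#'
#' @param matrix A [feature_matrix()].
#' @param annotations An [annotation_table()].
#' @param role Which annotation column the matrix rows key:
#'   `"compound"` or `"pathway"`.
#' @return A list with elements `matrix` (duplicates removed), `annotations`
#'   (re-pointed, duplicates collapsed), and `map` (named character vector,
#'   original ID -> representative ID, identity entries included).
#' @export
deduplicate <- function(matrix, annotations, role = c("compound", "pathway")) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(annotations, "annotation_table"))
  role <- match.arg(role)
  v <- matrix$values
  ids <- rownames(v)
  key <- if (ncol(v)) apply(v, 1L, paste, collapse = "\r") else
    rep("", nrow(v))
  groups <- split(ids, key)
  map <- character(0)
  for (g in groups) {
    rep_id <- g[order(g, method = "radix")][1L]
    map[g] <- rep_id
  }
  keep_ids <- sort(unique(unname(map)), method = "radix")
  out_m <- feature_matrix(v[keep_ids, , drop = FALSE],
                          normalized = matrix$normalized)
  col <- paste0(role, "_id")
  ann <- annotations
  hit <- ann[[col]] %in% names(map)
  ann[[col]][hit] <- unname(map[ann[[col]][hit]])
  out_a <- annotation_table(ann$compound_id, ann$pathway_id)
  list(matrix = out_m, annotations = out_a, map = map)
}

#' Normalize a raw count matrix by column maxima
#'
#' Each column is divided by its maximum over the corpus; all-zero columns
#' stay zero.  Every value of the result lies in `[0, 1]` and every nonzero
#' column attains 1.  Applied separately to compound and pathway matrices.
#'
#' @param matrix A raw [feature_matrix()].
#' @return A normalized [feature_matrix()].
#' @export
normalize_features <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  if (ncol(v) && nrow(v)) {
    cmax <- apply(v, 2L, max)
    scale <- ifelse(cmax > 0, cmax, 1)
    v <- sweep(v, 2L, scale, "/")
  }
  feature_matrix(v, normalized = TRUE)
}

#' Cross-join compounds and pathways into a labeled dataset
#'
#' Forms the full Cartesian product of compound rows and pathway rows: one
#' entry per (compound, pathway) pair, labeled `TRUE` exactly when the pair
#' is in the annotation set.  Entries are ordered compound-major: entry
#' `e` (1-based) pairs compound `(e - 1) %/% P + 1` with pathway
#' `(e - 1) %% P + 1`, `P` the number of pathways.  Annotation pairs whose
#' compound or pathway is not a retained matrix row are ignored.
#'
#' @param compound_matrix,pathway_matrix [feature_matrix()] objects
#'   (deduplicated and normalized in the standard pipeline).
#' @param annotations An [annotation_table()].
#' @return An object of class `xjoin_dataset` with the two matrices, the
#'   logical `labels` vector of length `|C| * |P|`, the retained
#'   `annotations`, and the counts `n_compounds`, `n_pathways`, `n_entries`.
#' @export
cross_join <- function(compound_matrix, pathway_matrix, annotations) {
  stopifnot(inherits(compound_matrix, "feature_matrix"),
            inherits(pathway_matrix, "feature_matrix"),
            inherits(annotations, "annotation_table"))
  C <- nrow(compound_matrix$values)
  P <- nrow(pathway_matrix$values)
  if (C == 0L || P == 0L) {
    stop("cross_join: empty compound or pathway matrix", call. = FALSE)
  }
  n <- as.double(C) * as.double(P)
  if (n > .Machine$integer.max) {
    stop("cross_join: entry count exceeds vector capacity", call. = FALSE)
  }
  labels <- logical(n)
  ci <- match(annotations$compound_id, entity_ids(compound_matrix))
  pi <- match(annotations$pathway_id, entity_ids(pathway_matrix))
  ok <- !is.na(ci) & !is.na(pi)
  labels[(ci[ok] - 1) * P + pi[ok]] <- TRUE
  retained <- annotation_table(annotations$compound_id[ok],
                               annotations$pathway_id[ok])
  structure(list(compounds = compound_matrix, pathways = pathway_matrix,
                 labels = labels, annotations = retained,
                 n_compounds = C, n_pathways = P, n_entries = n),
            class = "xjoin_dataset")
}

#' @export
print.xjoin_dataset <- function(x, ...) {
  cat(sprintf(paste0("<xjoin_dataset> %d compounds x %d pathways = %s",
                     " entries (%s positive, %.3g%%)\n"),
              x$n_compounds, x$n_pathways,
              format(x$n_entries, big.mark = ","),
              format(sum(x$labels), big.mark = ","),
              100 * sum(x$labels) / x$n_entries))
  invisible(x)
}

# (compound, pathway) row indices of given entry indices.
.entry_pairs <- function(dataset, idx) {
  P <- dataset$n_pathways
  list(compound = (idx - 1L) %/% P + 1L, pathway = (idx - 1L) %% P + 1L)
}

#' Materialize concatenated feature vectors for dataset entries
#'
#' Returns the model-input matrix for the requested entries: each row is the
#' compound feature row concatenated with the pathway feature row.  Column
#' names are prefixed `cmpd:` / `pway:` to keep them distinct.
#'
#' @param dataset An [cross_join()] dataset.
#' @param idx Integer entry indices (default: all entries).
#' @return A numeric matrix with `length(idx)` rows.
#' @export
entry_features <- function(dataset, idx = seq_len(dataset$n_entries)) {
  stopifnot(inherits(dataset, "xjoin_dataset"))
  pr <- .entry_pairs(dataset, as.integer(idx))
  cm <- dataset$compounds$values[pr$compound, , drop = FALSE]
  pm <- dataset$pathways$values[pr$pathway, , drop = FALSE]
  colnames(cm) <- paste0("cmpd:", colnames(dataset$compounds$values))
  colnames(pm) <- paste0("pway:", colnames(dataset$pathways$values))
  out <- cbind(cm, pm)
  rownames(out) <- NULL
  out
}

#' Assign hierarchy levels to pathways
#'
#' Roots (pathways with no parent) are level 1; every other pathway's level
#' is one more than the minimum level among its parents, i.e. 1 plus the
#' shortest root path.  Pathways listed in `ids` but absent from the
#' hierarchy are assigned level 1 with a message.  Display labels group
#' levels 6 and deeper as `"L6+"`.
#'
#' @param hierarchy A [pathway_hierarchy()].
#' @param ids Optional character vector of additional pathway IDs that must
#'   appear in the map (e.g. every annotated pathway).
#' @return An object of class `level_map`: list with named integer vector
#'   `level` and named character vector `display`.
#' @export
assign_levels <- function(hierarchy, ids = NULL) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  parent <- hierarchy$edges$parent
  child <- hierarchy$edges$child
  nodes <- union(parent, child)
  level <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  roots <- setdiff(nodes, child)
  level[roots] <- 1L
  queue <- roots
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- child[parent == v]
    for (w in kids) {
      cand <- level[v] + 1L
      if (is.na(level[w]) || cand < level[w]) {
        level[w] <- cand
        queue <- c(queue, w)
      }
    }
  }
  extra <- setdiff(ids, nodes)
  if (length(extra)) {
    message("assign_levels: ", length(extra),
            " pathway(s) absent from the hierarchy assigned level 1")
    level[extra] <- 1L
  }
  level <- level[order(names(level), method = "radix")]
  display <- ifelse(level >= 6L, "L6+", paste0("L", level))
  names(display) <- names(level)
  structure(list(level = level, display = display), class = "level_map")
}

#' @export
print.level_map <- function(x, ...) {
  cat("<level_map>", length(x$level), "pathways\n")
  print(table(x$display))
  invisible(x)
}

#' Restrict a cross-join dataset to pathways at or below a hierarchy level
#'
#' Pathways with level below `min_level` are removed and the cross join is
#' rebuilt over the remaining pathways; compounds are unchanged.
#' `min_level = 1` is the identity (the full dataset).  Pathways missing
#' from the level map are treated as level 1.
#'
#' @param dataset An [cross_join()] dataset.
#' @param levels A [assign_levels()] level map.
#' @param min_level Positive integer; the standard subsets use 1, 2, or 3.
#' @return An `xjoin_dataset` over the retained pathways.
#' @export
subset_by_level <- function(dataset, levels, min_level) {
  stopifnot(inherits(dataset, "xjoin_dataset"), inherits(levels, "level_map"))
  min_level <- as.integer(min_level)
  stopifnot(length(min_level) == 1L, min_level >= 1L)
  pids <- entity_ids(dataset$pathways)
  lv <- levels$level[pids]
  lv[is.na(lv)] <- 1L
  keep <- lv >= min_level
  if (!any(keep)) {
    stop("subset_by_level: no pathways at level >= ", min_level,
         call. = FALSE)
  }
  sub <- feature_matrix(dataset$pathways$values[keep, , drop = FALSE],
                        normalized = dataset$pathways$normalized)
  cross_join(dataset$compounds, sub, dataset$annotations)
}

#' Build the standard pipeline dataset from graphs and annotations
#'
#' Runs the fixed pipeline order: featurize compounds, aggregate pathway
#' features, deduplicate compounds then pathways (on raw counts, merging
#' annotations onto lexicographically smallest representatives), normalize
#' both matrices by column maxima, and cross-join.  Annotation pairs whose
#' compound has no graph are dropped with a message.
#'
#' @param graphs List of [molecule_graph()] (already parsed; see
#'   [parse_molfile()]).
#' @param annotations An [annotation_table()].
#' @param hierarchy Optional [pathway_hierarchy()]; when given, levels are
#'   assigned and the dataset can be restricted with `min_level`.
#' @param min_level Minimum hierarchy level to retain (default 1 = all).
#' @param max_radius Coloring radius for [featurize_compounds()].
#' @return A list of class `pathway_dataset`: `dataset` (`xjoin_dataset`),
#'   `levels` (`level_map` or `NULL`), `compound_sizes`, `pathway_sizes`,
#'   and the dedup `maps`.
#' @export
build_pathway_dataset <- function(graphs, annotations, hierarchy = NULL,
                                  min_level = 1L, max_radius = 2L) {
  stopifnot(inherits(annotations, "annotation_table"))
  ids <- vapply(graphs, `[[`, character(1L), "compound_id")
  known <- annotations$compound_id %in% ids
  if (any(!known)) {
    message("build_pathway_dataset: dropped ", sum(!known),
            " annotation pair(s) without a parseable structure")
    annotations <- annotation_table(annotations$compound_id[known],
                                    annotations$pathway_id[known])
  }
  cmat <- featurize_compounds(graphs, max_radius)
  pmat <- aggregate_pathway_features(cmat, annotations)
  dd_c <- deduplicate(cmat, annotations, role = "compound")
  dd_p <- deduplicate(pmat, dd_c$annotations, role = "pathway")
  ann <- dd_p$annotations
  cnorm <- normalize_features(dd_c$matrix)
  pnorm <- normalize_features(dd_p$matrix)
  ds <- cross_join(cnorm, pnorm, ann)
  lvls <- NULL
  if (!is.null(hierarchy)) {
    lvls <- assign_levels(hierarchy, ids = unique(ann$pathway_id))
    if (min_level > 1L) ds <- subset_by_level(ds, lvls, min_level)
  } else if (min_level > 1L) {
    stop("min_level > 1 requires a hierarchy", call. = FALSE)
  }
  sizes <- stats::setNames(vapply(graphs, compound_size, integer(1L)), ids)
  structure(list(dataset = ds, levels = lvls,
                 compound_sizes = sizes,
                 pathway_sizes = pathway_size(ann, sizes),
                 maps = list(compound = dd_c$map, pathway = dd_p$map)),
            class = "pathway_dataset")
}

#' @export
print.pathway_dataset <- function(x, ...) {
  cat("<pathway_dataset>\n")
  print(x$dataset)
  if (!is.null(x$levels)) print(x$levels)
  invisible(x)
}
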