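# Confusion-matrix metrics at every scope, the summed-count "overall MCC"
# aggregation, iteration summaries, size reports, and effect sizes.
#
# A metric whose denominator vanishes is "undefined" and reported as
# NA_real_, never silently 0: with very sparse positives a single compound
# or pathway can easily have an all-zero margin in one iteration.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = as.double(tp), tn = as.double(tn),
         fp = as.double(fp), fn = as.double(fn))
  if (anyNA(v) || any(v < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%g tn=%g fp=%g fn=%g\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Tally a confusion matrix from labels and predictions
#'
#' @param labels,predictions Logical vectors of equal length.
#' @return A [confusion_counts()].
#' @export
confusion <- function(labels, predictions) {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  stopifnot(length(labels) == length(predictions))
  confusion_counts(tp = sum(predictions & labels),
                   tn = sum(!predictions & !labels),
                   fp = sum(predictions & !labels),
                   fn = sum(!predictions & labels))
}

.as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  if (is.numeric(c) && length(c) == 4L) {
    nm <- names(c)
    if (is.null(nm)) nm <- c("tp", "tn", "fp", "fn")
    return(confusion_counts(c[["tp"]] %||% c[1L], c[["tn"]] %||% c[2L],
                            c[["fp"]] %||% c[3L], c[["fn"]] %||% c[4L]))
  }
  stop("expected confusion_counts or a length-4 numeric vector",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.  Returns
#' `NA_real_` ("undefined") whenever any of the four marginal factors is
#' zero, which happens e.g. when a split leaves a compound or pathway with
#' no positive entries (overall TP + FN = 0).
#'
#' @param c A [confusion_counts()] or named numeric vector
#'   `c(tp=, tn=, fp=, fn=)`.
#' @return A number in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
mcc <- function(c) {
  c <- .as_counts(c)
  s <- c((c$tp + c$fp), (c$tp + c$fn), (c$tn + c$fp), (c$tn + c$fn))
  if (any(s == 0)) return(NA_real_)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(prod(s))
}

#' Standard binary-classification metrics from a confusion matrix
#'
#' Computes MCC, accuracy, F1, precision, recall, and specificity; each
#' metric is `NA_real_` on a zero denominator.
#'
#' @inheritParams mcc
#' @return A list of class `metric_set`.
#' @export
metric_set <- function(c) {
  c <- .as_counts(c)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  total <- c$tp + c$tn + c$fp + c$fn
  structure(list(
    mcc = mcc(c),
    accuracy = safe_div(c$tp + c$tn, total),
    f1 = safe_div(2 * c$tp, 2 * c$tp + c$fp + c$fn),
    precision = safe_div(c$tp, c$tp + c$fp),
    recall = safe_div(c$tp, c$tp + c$fn),
    specificity = safe_div(c$tn, c$tn + c$fp),
    counts = c), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf(paste0("<metric_set> mcc=%s acc=%s f1=%s precision=%s ",
                     "recall=%s specificity=%s\n"),
              fmt(x$mcc), fmt(x$accuracy), fmt(x$f1), fmt(x$precision),
              fmt(x$recall), fmt(x$specificity)))
  invisible(x)
}

#' Overall (summed-count) metrics at a chosen scope
#'
#' Sums TP/TN/FP/FN across all CV iterations -- and, for the level scope,
#' across every pathway in the hierarchy level -- into a single confusion
#' matrix, then computes the metrics once.  The MCC of this summed matrix is
#' the overall MCC (oMCC).  With a single iteration and the dataset scope
#' this reduces to that iteration's metrics.
#'
#' @param cv A [run_cv()] result.
#' @param scope `"dataset"`, `"compound"`, `"pathway"`, or `"level"`.
#' @param entity Entity ID for the compound/pathway scopes, or a display
#'   level label (`"L1"` .. `"L5"`, `"L6+"`) for the level scope; ignored
#'   for `"dataset"`.
#' @return A [metric_set()].
#' @export
overall_metric <- function(cv, scope = c("dataset", "compound", "pathway",
                                         "level"), entity = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  scope <- match.arg(scope)
  counts <- switch(scope,
    dataset = colSums(cv$overall),
    compound = {
      if (!entity %in% dimnames(cv$compound)[[2L]]) {
        stop("unknown compound: ", entity, call. = FALSE)
      }
      colSums(cv$compound[, entity, , drop = FALSE][, 1L, ])
    },
    pathway = {
      if (!entity %in% dimnames(cv$pathway)[[2L]]) {
        stop("unknown pathway: ", entity, call. = FALSE)
      }
      colSums(cv$pathway[, entity, , drop = FALSE][, 1L, ])
    },
    level = {
      sel <- names(cv$levels)[cv$levels == entity]
      if (!length(sel)) stop("no pathways at level ", entity, call. = FALSE)
      apply(cv$pathway[, sel, , drop = FALSE], 3L, sum)
    })
  metric_set(confusion_counts(counts[["tp"]], counts[["tn"]],
                              counts[["fp"]], counts[["fn"]]))
}

#' Per-iteration MCC values of a CV run
#'
#' @param cv A [run_cv()] result.
#' @return Numeric vector, one (possibly `NA`) MCC per iteration.
#' @export
iteration_mcc <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  apply(cv$overall, 1L, function(r)
    mcc(confusion_counts(r[["tp"]], r[["tn"]], r[["fp"]], r[["fn"]])))
}

#' Summarize per-iteration test-set MCC
#'
#' Mean, median, and sample (n-1) standard deviation of the per-iteration
#' overall-test-set MCC values; undefined iterations are excluded with a
#' message.
#'
#' @param cv A [run_cv()] result.
#' @return A list of class `iteration_summary` with `mean_mcc`,
#'   `median_mcc`, `sd_mcc`, `n_iterations`.
#' @export
summarize_iterations <- function(cv) {
  vals <- iteration_mcc(cv)
  if (anyNA(vals)) {
    message("summarize_iterations: excluded ", sum(is.na(vals)),
            " iteration(s) with undefined MCC")
    vals <- vals[!is.na(vals)]
  }
  structure(list(mean_mcc = mean(vals), median_mcc = stats::median(vals),
                 sd_mcc = stats::sd(vals), n_iterations = length(vals)),
            class = "iteration_summary")
}

#' @export
print.iteration_summary <- function(x, ...) {
  cat(sprintf(
    "<iteration_summary> n=%d mean MCC=%.4f median MCC=%.4f sd=%.4f\n",
    x$n_iterations, x$mean_mcc, x$median_mcc,
    if (is.na(x$sd_mcc)) NA else x$sd_mcc))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) summarize_iterations(object)

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iteration(s), %d compounds, %d pathways\n",
              nrow(x$overall), dim(x$compound)[2L], dim(x$pathway)[2L]))
  invisible(x)
}

#' Cohen's d effect size from summary statistics
#'
#' `(mean_a - mean_b) / s_pooled` with the pooled standard deviation
#' `sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`; with equal
#' group sizes this equals the root-mean-square convention.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return The standardized mean difference (signed).
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2L, n_b >= 2L, sd_a >= 0, sd_b >= 0)
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  (mean_a - mean_b) / pooled
}

#' Relative improvement in percent
#'
#' `100 * (mean_new - mean_ref) / mean_ref`: the improvement of a new mean
#' over a reference mean, on the reference scale.
#'
#' @param mean_new,mean_ref Numbers; `mean_ref` must be nonzero.
#' @return Percentage (signed).
#' @export
relative_improvement <- function(mean_new, mean_ref) {
  stopifnot(mean_ref != 0)
  100 * (mean_new - mean_ref) / mean_ref
}

#' Entity size versus overall MCC report
#'
#' Joins compound and pathway sizes with their per-entity overall
#' (summed-count) MCC and, for pathways, the hierarchy display level --
#' the table behind size-vs-oMCC scatterplots.
#'
#' @param cv A [run_cv()] result.
#' @param compound_sizes Named integer vector, compound ID -> heavy atoms.
#' @param pathway_sizes Named integer vector, pathway ID -> summed member
#'   size (see [pathway_size()]).
#' @return A data frame with columns `entity_id`, `type`, `size`, `omcc`
#'   (`NA` when undefined), `level`.
#' @export
size_report <- function(cv, compound_sizes, pathway_sizes) {
  stopifnot(inherits(cv, "cv_result"))
  cids <- dimnames(cv$compound)[[2L]]
  pids <- dimnames(cv$pathway)[[2L]]
  omcc_of <- function(scope, id) overall_metric(cv, scope, id)$mcc
  rows_c <- data.frame(
    entity_id = cids, type = "compound",
    size = as.integer(compound_sizes[cids]),
    omcc = vapply(cids, function(id) omcc_of("compound", id), numeric(1L)),
    level = NA_character_, stringsAsFactors = FALSE)
  rows_p <- data.frame(
    entity_id = pids, type = "pathway",
    size = as.integer(pathway_sizes[pids]),
    omcc = vapply(pids, function(id) omcc_of("pathway", id), numeric(1L)),
    level = unname(cv$levels[pids]), stringsAsFactors = FALSE)
  out <- rbind(rows_c, rows_p)
  rownames(out) <- NULL
  out
}
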