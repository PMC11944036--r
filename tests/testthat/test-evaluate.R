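# Independent oracles coded from first principles, against which the
# package implementations are checked.
mcc_oracle <- function(tp, tn, fp, fn) {
  # MCC equals the Pearson correlation of the binary label/prediction vectors
  labels <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  preds <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  suppressWarnings(stats::cor(labels, preds))
}

random_counts <- function(n, max = 30L, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:max, 4L * n, replace = TRUE), n, 4L,
         dimnames = list(NULL, c("tp", "tn", "fp", "fn")))
}

test_that("confusion tallies the four cells, matching a nested-loop oracle", {
  expect_equal(unlist(unclass(confusion(c(TRUE, FALSE), c(TRUE, FALSE)))),
               c(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(unclass(confusion(c(TRUE, FALSE), c(FALSE, TRUE)))),
               c(tp = 0, tn = 0, fp = 1, fn = 1))
  set.seed(23)
  labels <- runif(100L) < 0.3
  preds <- runif(100L) < 0.5
  cm <- confusion(labels, preds)
  cells <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(labels)) {
    cell <- if (labels[i] && preds[i]) "tp" else if (!labels[i] && !preds[i])
      "tn" else if (preds[i]) "fp" else "fn"
    cells[cell] <- cells[cell] + 1L
  }
  expect_equal(unlist(unclass(cm)), as.numeric(cells), ignore_attr = TRUE)
})

test_that("mcc matches hand values and is undefined exactly on zero marginals", {
  expect_equal(mcc(confusion_counts(1, 1, 0, 0)), 1.0)
  expect_equal(mcc(confusion_counts(1, 1, 1, 1)), 0.0)
  expect_true(is.na(mcc(confusion_counts(0, 5, 0, 0))))  # no positives at all
  expect_true(is.na(mcc(confusion_counts(3, 0, 2, 0))))  # no negative labels
})

test_that("mcc and metric_set agree with independent oracles on 1000 random matrices", {
  cnt <- random_counts(1000L, seed = 31L)
  for (i in seq_len(nrow(cnt))) {
    cc <- confusion_counts(cnt[i, 1L], cnt[i, 2L], cnt[i, 3L], cnt[i, 4L])
    marg <- c(cnt[i, 1L] + cnt[i, 3L], cnt[i, 1L] + cnt[i, 4L],
              cnt[i, 2L] + cnt[i, 3L], cnt[i, 2L] + cnt[i, 4L])
    m <- mcc(cc)
    if (any(marg == 0)) {
      expect_true(is.na(m))
    } else {
      expect_equal(m, mcc_oracle(cnt[i, 1L], cnt[i, 2L], cnt[i, 3L],
                                 cnt[i, 4L]), tolerance = 1e-12)
      expect_true(abs(m) <= 1)
    }
    ms <- metric_set(cc)
    tp <- unname(cnt[i, 1L]); tn <- unname(cnt[i, 2L])
    fp <- unname(cnt[i, 3L]); fn <- unname(cnt[i, 4L])
    ref <- list(
      accuracy = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn),
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn),
      precision = if (tp + fp > 0) tp / (tp + fp),
      recall = if (tp + fn > 0) tp / (tp + fn),
      specificity = if (tn + fp > 0) tn / (tn + fp))
    for (nm in names(ref)) {
      if (is.null(ref[[nm]])) expect_true(is.na(ms[[nm]]))
      else expect_equal(ms[[nm]], ref[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("metric_set handles perfect and degenerate confusion matrices", {
  perfect <- metric_set(confusion_counts(1, 1, 0, 0))
  for (nm in c("mcc", "accuracy", "f1", "precision", "recall",
               "specificity")) {
    expect_equal(perfect[[nm]], 1.0)
  }
  deg <- metric_set(confusion_counts(0, 1, 0, 1))
  expect_equal(deg$recall, 0)
  expect_equal(deg$specificity, 1)
  expect_true(is.na(deg$precision))
})

test_that("summed-count aggregation matches hand arithmetic and reduces for one iteration", {
  td <- tiny_dataset(seed = 37L, n_compounds = 16L, n_pathways = 3L)
  cv <- run_cv(td$pd$dataset, 1L, fast_mlp(), base_seed = 2L)
  it1 <- mcc(confusion_counts(cv$overall[1L, "tp"], cv$overall[1L, "tn"],
                              cv$overall[1L, "fp"], cv$overall[1L, "fn"]))
  om <- overall_metric(cv, "dataset")$mcc
  expect_identical(is.na(om), is.na(it1))
  if (!is.na(om)) expect_equal(om, it1)

  # two hand-made iterations: (1,1,0,0) + (0,1,1,0) -> (1,2,1,0)
  cv2 <- cv
  cv2$overall <- rbind(c(tp = 1, tn = 1, fp = 0, fn = 0),
                       c(tp = 0, tn = 1, fp = 1, fn = 0))
  expect_equal(overall_metric(cv2, "dataset")$mcc,
               (1 * 2 - 0 * 1) / sqrt(2 * 1 * 3 * 2), tolerance = 1e-12)
})

test_that("level-scope counts equal the sum of the level's per-pathway sums", {
  td <- tiny_dataset(seed = 41L, n_compounds = 20L, n_pathways = 6L)
  cv <- run_cv(td$pd$dataset, 2L, fast_mlp(), base_seed = 6L,
               levels = td$pd$levels)
  for (lv in unique(cv$levels)) {
    sel <- names(cv$levels)[cv$levels == lv]
    by_pathway <- rowSums(vapply(sel, function(p)
      colSums(cv$pathway[, p, , drop = FALSE][, 1L, ]), numeric(4L)))
    lvl_counts <- overall_metric(cv, "level", lv)$counts
    expect_equal(unlist(unclass(lvl_counts)), by_pathway,
                 ignore_attr = TRUE)
  }
})

test_that("iteration summaries match base-R statistics and drop undefined MCCs", {
  td <- tiny_dataset(seed = 43L)
  cv <- run_cv(td$pd$dataset, 3L, fast_mlp(), base_seed = 8L)
  cv$overall <- rbind(c(tp = 9, tn = 1, fp = 0, fn = 0),
                      c(tp = 8, tn = 2, fp = 1, fn = 1),
                      c(tp = 0, tn = 10, fp = 0, fn = 0))   # undefined
  expect_message(s <- summarize_iterations(cv), "excluded 1")
  vals <- c(mcc(confusion_counts(9, 1, 0, 0)),
            mcc(confusion_counts(8, 2, 1, 1)))
  expect_equal(s$mean_mcc, mean(vals), tolerance = 1e-12)
  expect_equal(s$median_mcc, median(vals), tolerance = 1e-12)
  expect_equal(s$sd_mcc, sd(vals), tolerance = 1e-12)
  expect_equal(s$n_iterations, 2L)
})

test_that("identical per-iteration MCCs summarize with zero spread", {
  td <- tiny_dataset(seed = 47L)
  cv <- run_cv(td$pd$dataset, 1L, fast_mlp(), base_seed = 1L)
  cv$overall <- rbind(c(tp = 2, tn = 7, fp = 1, fn = 0),
                      c(tp = 2, tn = 7, fp = 1, fn = 0),
                      c(tp = 2, tn = 7, fp = 1, fn = 0))
  s <- summarize_iterations(cv)
  expect_equal(s$sd_mcc, 0)
  expect_equal(s$mean_mcc, s$median_mcc)
})

test_that("cohens_d follows the pooled-SD closed forms", {
  expect_equal(cohens_d(0.5, 0.1, 10L, 0.5, 0.2, 10L), 0)
  expect_equal(cohens_d(1.2, 0.3, 50L, 1.0, 0.3, 70L), 0.2 / 0.3,
               tolerance = 1e-12)
  set.seed(53)
  a <- rnorm(40L); b <- rnorm(40L, 1)
  d <- cohens_d(mean(a), sd(a), 40L, mean(b), sd(b), 40L)
  pooled <- sqrt((39 * var(a) + 39 * var(b)) / 78)
  expect_equal(d, (mean(a) - mean(b)) / pooled, tolerance = 1e-12)
})

test_that("relative improvement is computed on the reference mean", {
  expect_equal(relative_improvement(1.1, 1.0), 10)
  expect_equal(relative_improvement(0.8, 0.8), 0)
  expect_equal(relative_improvement(0.9, 1.2), -25)
})

test_that("size_report joins sizes, per-entity oMCC, and level labels", {
  td <- tiny_dataset(seed = 59L, n_compounds = 12L, n_pathways = 4L)
  cv <- run_cv(td$pd$dataset, 2L, fast_mlp(), base_seed = 3L,
               levels = td$pd$levels)
  rep <- size_report(cv, td$pd$compound_sizes, td$pd$pathway_sizes)
  expect_equal(nrow(rep),
               dim(cv$compound)[2L] + dim(cv$pathway)[2L])
  pw <- rep[rep$type == "pathway", ]
  expect_identical(pw$level, unname(cv$levels[pw$entity_id]))
  expect_true(all(is.na(rep$level[rep$type == "compound"])))
  # spot-check one compound's oMCC against the summed-count definition
  cid <- rep$entity_id[1L]
  counts <- colSums(cv$compound[, cid, ])
  expect_equal(rep$omcc[1L],
               mcc(confusion_counts(counts["tp"], counts["tn"],
                                    counts["fp"], counts["fn"])))
})
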