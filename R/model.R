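# Stratified shuffle-splitting, a small feed-forward network trained with
# class-weighted binary cross-entropy, and the repeated cross-validation
# driver that records confusion counts at every scope.

#' Stratified train/test shuffle split
#'
#' Draws a test set of `round(n * test_fraction)` entries whose positive
#' count is chosen so that the positive proportion in the test set is as
#' close as possible to the positive proportion in the train set, under
#' integer rounding.  Membership within each class is sampled uniformly from
#' the seeded RNG; the same seed always reproduces the same split.
#'
#' @param labels Logical vector (must contain both classes).
#' @param test_fraction Target test share, default 0.1 (the 9:1 convention).
#' @param seed Integer RNG seed.
#' @return An object of class `split_spec`: sorted integer vectors `train`
#'   and `test` (disjoint, covering all entries), plus the seed and
#'   fraction.
#' @export
stratified_split <- function(labels, test_fraction = 0.1, seed = 1L) {
  labels <- as.logical(labels)
  n <- length(labels)
  npos <- sum(labels)
  nneg <- n - npos
  if (npos == 0L || nneg == 0L) {
    stop("stratification error: labels contain a single class", call. = FALSE)
  }
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- max(1L, min(n - 1L, as.integer(round(n * test_fraction))))
  t_min <- max(0L, n_test - nneg)
  t_max <- min(npos, n_test)
  cand <- unique(pmin(pmax(c(floor(npos * n_test / n),
                             ceiling(npos * n_test / n)), t_min), t_max))
  prop_gap <- function(t) abs(t / n_test - (npos - t) / (n - n_test))
  gaps <- vapply(cand, prop_gap, numeric(1L))
  t_pos <- min(cand[gaps == min(gaps)])
  pos_idx <- which(labels)
  neg_idx <- which(!labels)
  set.seed(seed)
  test_pos <- if (t_pos > 0L) pos_idx[sample.int(npos, t_pos)] else integer(0)
  t_neg <- n_test - t_pos
  test_neg <- if (t_neg > 0L) neg_idx[sample.int(nneg, t_neg)] else integer(0)
  test <- sort(c(test_pos, test_neg))
  train <- setdiff(seq_len(n), test)
  structure(list(train = train, test = test, seed = as.integer(seed),
                 test_fraction = test_fraction),
            class = "split_spec")
}

#' Configuration for the MLP classifier
#'
#' Hyperparameters of [fit_mlp()].  Defaults: two rectified-linear hidden
#' layers, dropout 0.1, Adam with learning rate 1e-3, early stopping with
#' patience 5 on a held-out slice of the training set, and `"balanced"`
#' positive-class weighting (negatives/positives), which compensates for the
#' very low positive prevalence of cross-join datasets.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param dropout Dropout probability in `[0, 1)` applied to hidden
#'   activations during training.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum passes over the training data; 0 returns an
#'   untrained network.
#' @param batch_size Minibatch size.
#' @param positive_class_weight `"balanced"` or a positive number
#'   multiplying the loss of positive entries.
#' @param weight_decay Decoupled L2 penalty applied to the weight matrices
#'   each Adam step (AdamW); discourages memorizing individual
#'   compound-pathway pairs in favor of shared structure.
#' @param decision_threshold Probability cutoff for the boolean prediction;
#'   probabilities `>=` the threshold classify as `TRUE`.
#' @param patience Early-stopping patience, in epochs.
#' @param val_fraction Share of the training data held out for early
#'   stopping (0 disables early stopping).
#' @param seed Default RNG seed for initialization and shuffling.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(256L, 128L), dropout = 0.1,
                       learning_rate = 1e-3, max_epochs = 30L,
                       batch_size = 256L, positive_class_weight = "balanced",
                       decision_threshold = 0.5, patience = 5L,
                       val_fraction = 0.1, weight_decay = 0, seed = 1L) {
  hidden_sizes <- as.integer(hidden_sizes)
  stopifnot(length(hidden_sizes) >= 1L, all(hidden_sizes >= 1L),
            dropout >= 0, dropout < 1, learning_rate > 0,
            max_epochs >= 0L, batch_size >= 1L,
            decision_threshold > 0, decision_threshold < 1,
            patience >= 1L, val_fraction >= 0, val_fraction < 1,
            weight_decay >= 0)
  if (!identical(positive_class_weight, "balanced")) {
    stopifnot(is.numeric(positive_class_weight), positive_class_weight > 0)
  }
  structure(list(hidden_sizes = hidden_sizes, dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 positive_class_weight = positive_class_weight,
                 decision_threshold = decision_threshold,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

# Forward pass without dropout; returns the logit vector.
.mlp_forward <- function(net, x) {
  a <- x
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]]
    z <- z + matrix(net$b[[l]], nrow(z), ncol(z), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
  }
  as.numeric(a)
}

.softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' Fit the MLP binary classifier
#'
#' Trains a fully connected network with rectified-linear hidden layers on
#' concatenated compound-pathway feature rows, minimizing class-weighted
#' binary cross-entropy with Adam on shuffled minibatches.  When
#' `val_fraction > 0` a seeded slice of the training rows is held out and
#' training stops once the held-out loss has not improved for `patience`
#' epochs, restoring the best weights.  All randomness (initialization,
#' shuffling, dropout) derives from `seed`, so fits are reproducible.
#'
#' @param x Numeric matrix of training rows.
#' @param y Logical labels, one per row.
#' @param config An [mlp_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return An object of class `mlp_net` holding the weights and metadata.
#' @export
fit_mlp <- function(x, y, config = mlp_config(), seed = config$seed) {
  stopifnot(is.matrix(x), inherits(config, "mlp_config"))
  y <- as.logical(y)
  stopifnot(length(y) == nrow(x))
  d <- ncol(x)
  sizes <- c(d, config$hidden_sizes, 1L)
  L <- length(sizes) - 1L
  set.seed(as.integer(seed))
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  net <- structure(list(W = W, b = b, config = config, input_dim = d,
                        input_names = colnames(x), seed = as.integer(seed),
                        trained = FALSE, epochs_run = 0L),
                   class = "mlp_net")
  if (config$max_epochs == 0L) return(net)

  pw <- config$positive_class_weight
  if (identical(pw, "balanced")) {
    pw <- if (sum(y) > 0L) (length(y) - sum(y)) / sum(y) else 1
  }
  wts <- ifelse(y, pw, 1)

  n <- nrow(x)
  val_idx <- integer(0)
  if (config$val_fraction > 0 && n >= 50L) {
    nval <- max(1L, floor(n * config$val_fraction))
    val_idx <- sample.int(n, nval)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]; wtr <- wts[tr_idx]
  xval <- x[val_idx, , drop = FALSE]; yval <- y[val_idx]
  wval <- wts[val_idx]

  wloss <- function(z, yy, ww) sum(ww * (.softplus(z) - yy * z)) / sum(ww)

  mW <- lapply(W, function(m) m * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  best_loss <- Inf
  best <- list(W = W, b = b)
  stall <- 0L
  drop_p <- config$dropout

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(length(ytr))
    starts <- seq(1L, length(ytr), by = config$batch_size)
    for (s in starts) {
      rows <- perm[s:min(s + config$batch_size - 1L, length(ytr))]
      a <- list(xtr[rows, , drop = FALSE])
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        z <- a[[l]] %*% W[[l]]
        z <- z + matrix(b[[l]], nrow(z), ncol(z), byrow = TRUE)
        if (l < L) {
          h <- pmax(z, 0)
          if (drop_p > 0) {
            mk <- (matrix(stats::runif(length(h)), nrow(h)) >= drop_p) /
              (1 - drop_p)
            h <- h * mk
            masks[[l]] <- mk
          }
          a[[l + 1L]] <- h
        } else {
          a[[l + 1L]] <- z
        }
      }
      z <- as.numeric(a[[L + 1L]])
      if (any(!is.finite(z))) {
        stop("training-divergence error: non-finite loss; config: ",
             paste(deparse(unclass(config)), collapse = ""), call. = FALSE)
      }
      ww <- wtr[rows]
      delta <- matrix(ww * (stats::plogis(z) - ytr[rows]) / sum(ww), ncol = 1L)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          act <- a[[l]]
          delta <- delta * (act > 0)
          if (drop_p > 0) delta <- delta * masks[[l - 1L]]
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps) - lr * config$weight_decay * W[[l]]
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    net$W <- W; net$b <- b
    mon <- if (length(val_idx)) {
      wloss(.mlp_forward(net, xval), yval, wval)
    } else {
      wloss(.mlp_forward(net, xtr), ytr, wtr)
    }
    if (!is.finite(mon)) {
      stop("training-divergence error: non-finite loss; config: ",
           paste(deparse(unclass(config)), collapse = ""), call. = FALSE)
    }
    net$epochs_run <- epoch
    if (mon < best_loss - 1e-9) {
      best_loss <- mon
      best <- list(W = W, b = b)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  net$W <- best$W
  net$b <- best$b
  net$trained <- TRUE
  net
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("<mlp_net> input %d -> %s -> 1 (%s, %d epoch(s))\n",
              x$input_dim, paste(x$config$hidden_sizes, collapse = "-"),
              if (x$trained) "trained" else "untrained", x$epochs_run))
  invisible(x)
}

#' Predict pathway-involvement probabilities or classes
#'
#' @param object A fitted [fit_mlp()] network.
#' @param x Numeric matrix whose width matches the training input width.
#' @param type `"prob"` for probabilities in `[0, 1]`, `"class"` for the
#'   boolean decision (probability `>=` threshold).
#' @param threshold Decision threshold; defaults to the config value.
#' @param ... Unused.
#' @return Numeric or logical vector, one value per row of `x`.
#' @export
predict.mlp_net <- function(object, x, type = c("prob", "class"),
                            threshold = object$config$decision_threshold,
                            ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  if (ncol(x) != object$input_dim) {
    stop("shape error: input has ", ncol(x), " columns, model expects ",
         object$input_dim, call. = FALSE)
  }
  p <- stats::plogis(.mlp_forward(object, x))
  if (type == "prob") p else p >= threshold
}

#' Repeated stratified cross-validation of the MLP on a cross-join dataset
#'
#' Each iteration draws an independent seeded stratified shuffle split
#' (9:1 by default), trains a fresh network on the training entries, and
#' classifies the test entries.  Confusion counts are recorded per
#' iteration at the overall, per-compound, and per-pathway scopes (each
#' test entry is attributed to exactly one compound and one pathway), which
#' is what the summed-count "overall MCC" aggregation consumes.
#'
#' @param dataset An [cross_join()] dataset.
#' @param n_iterations Number of CV iterations (the reference protocol uses
#'   200 for the full dataset and 50 for level subsets).
#' @param config An [mlp_config()].
#' @param base_seed Integer; per-iteration seeds are derived from it.
#' @param levels Optional [assign_levels()] map used for level-scope
#'   aggregation.
#' @param test_fraction Test share per iteration, default 0.1.
#' @return An object of class `cv_result`: `overall` (iterations x 4 count
#'   matrix with columns tp/tn/fp/fn), `compound` and `pathway` (3-d count
#'   arrays iterations x entities x 4), `levels` (display label per
#'   pathway), the config and seeds.
#' @export
run_cv <- function(dataset, n_iterations, config = mlp_config(),
                   base_seed = 1L, levels = NULL, test_fraction = 0.1) {
  stopifnot(inherits(dataset, "xjoin_dataset"), n_iterations >= 1L)
  X <- entry_features(dataset)
  y <- dataset$labels
  cids <- entity_ids(dataset$compounds)
  pids <- entity_ids(dataset$pathways)
  nit <- as.integer(n_iterations)
  cnt_names <- c("tp", "tn", "fp", "fn")
  overall <- matrix(0, nit, 4L, dimnames = list(NULL, cnt_names))
  comp <- array(0, c(nit, length(cids), 4L),
                dimnames = list(NULL, cids, cnt_names))
  path <- array(0, c(nit, length(pids), 4L),
                dimnames = list(NULL, pids, cnt_names))
  seeds <- integer(nit)
  for (it in seq_len(nit)) {
    seed_it <- as.integer((as.double(base_seed) + 104729 * it) %% 2147483646) + 1L
    seeds[it] <- seed_it
    sp <- stratified_split(y, test_fraction, seed_it)
    net <- fit_mlp(X[sp$train, , drop = FALSE], y[sp$train], config,
                   seed = seed_it)
    pred <- predict(net, X[sp$test, , drop = FALSE], type = "class")
    truth <- y[sp$test]
    ind <- cbind(tp = as.numeric(pred & truth),
                 tn = as.numeric(!pred & !truth),
                 fp = as.numeric(pred & !truth),
                 fn = as.numeric(!pred & truth))
    overall[it, ] <- colSums(ind)
    pr <- .entry_pairs(dataset, sp$test)
    cs <- rowsum(ind, group = pr$compound)
    comp[it, as.integer(rownames(cs)), ] <- cs
    ps <- rowsum(ind, group = pr$pathway)
    path[it, as.integer(rownames(ps)), ] <- ps
  }
  lv <- if (!is.null(levels)) {
    d <- levels$display[pids]
    d[is.na(d)] <- "L1"
    stats::setNames(d, pids)
  } else {
    stats::setNames(rep("L1", length(pids)), pids)
  }
  structure(list(overall = overall, compound = comp, pathway = path,
                 levels = lv, config = config, base_seed = base_seed,
                 seeds = seeds, n_test = rowSums(overall)),
            class = "cv_result")
}
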