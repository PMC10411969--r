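## Bootstrap cross-validated classification accuracy for single neurons.
##
## The classifier is a diagonal LDA on the discharge rate in one time bin
## (one feature). Trials per condition are adjusted to T, the largest
## multiple of eight not exceeding the minimum trial count across all six
## conditions. Per bootstrap resample, T trials are drawn with replacement
## per condition, split into eight folds; per fold the classifier is fit on
## the training task's remaining 7/8 and tested on the held-out fold of the
## test task. The resample accuracy is the mean of the eight fold
## accuracies.
##
## With a single feature, balanced classes, and one pooled variance shared
## by all classes, the diagonal-LDA argmax reduces exactly to the
## nearest-class-mean rule; the fast engine exploits this and is verified
## against the general diag_lda path in the test suite.

MODES <- c("e2e", "o2o", "e2o", "o2e")

mode_tasks <- function(mode) {
  switch(match.arg(mode, MODES),
         e2e = c(train = "execution", test = "execution"),
         o2o = c(train = "observation", test = "observation"),
         e2o = c(train = "execution", test = "observation"),
         o2e = c(train = "observation", test = "execution"))
}

#' Cross-validated trial count
#'
#' Largest multiple of 8 not exceeding the minimum trial count across the
#' six conditions; `NA` if that is below 8.
#' @param cond_sizes integer vector of per-condition trial counts.
#' @return integer T or `NA_integer_`.
#' @export
cv_trial_count <- function(cond_sizes) {
  t8 <- (min(cond_sizes) %/% 8L) * 8L
  if (t8 < 8L) NA_integer_ else as.integer(t8)
}

## index matrices [n_boot x T] per class, drawn with replacement
draw_boot_indices <- function(sizes, T, n_boot) {
  lapply(sizes, function(nv)
    matrix(sample.int(nv, n_boot * T, replace = TRUE), n_boot, T))
}

## fast 1-D engine; vals_* are lists of 3 per-action value vectors,
## idx_* the matching index matrices
fast_accuracy <- function(vals_train, vals_test, idx_train, idx_test,
                          same_task, T, n_boot, train_folds = TRUE) {
  fs <- T %/% 8L
  Xtr <- lapply(1:3, function(k)
    matrix(vals_train[[k]][idx_train[[k]]], n_boot, T))
  Xte <- if (same_task) Xtr else
    lapply(1:3, function(k) matrix(vals_test[[k]][idx_test[[k]]], n_boot, T))
  S <- lapply(Xtr, rowSums)
  acc <- matrix(0, n_boot, 8L)
  for (f in 1:8) {
    cols <- ((f - 1L) * fs + 1L):(f * fs)
    mu <- lapply(1:3, function(k) {
      if (train_folds)
        (S[[k]] - rowSums(Xtr[[k]][, cols, drop = FALSE])) / (T - fs)
      else S[[k]] / T
    })
    ncorrect <- numeric(n_boot)
    for (k in 1:3) {
      xt <- Xte[[k]][, cols, drop = FALSE]
      d1 <- (xt - mu[[1L]])^2
      d2 <- (xt - mu[[2L]])^2
      d3 <- (xt - mu[[3L]])^2
      pred <- matrix(1L, n_boot, fs)
      best <- d1
      w <- d2 < best; pred[w] <- 2L; best[w] <- d2[w]
      w <- d3 < best; pred[w] <- 3L
      ncorrect <- ncorrect + rowSums(pred == k)
    }
    acc[, f] <- ncorrect / (3 * fs)
  }
  rowMeans(acc)
}

## reference engine: same resample geometry through diag_lda_fit/predict
reference_accuracy <- function(vals_train, vals_test, idx_train, idx_test,
                               same_task, T, n_boot, train_folds = TRUE) {
  fs <- T %/% 8L
  out <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xtr <- lapply(1:3, function(k) vals_train[[k]][idx_train[[k]][b, ]])
    xte <- if (same_task) xtr else
      lapply(1:3, function(k) vals_test[[k]][idx_test[[k]][b, ]])
    facc <- numeric(8)
    for (f in 1:8) {
      cols <- ((f - 1L) * fs + 1L):(f * fs)
      if (train_folds) {
        feat <- unlist(lapply(xtr, function(v) v[-cols]))
        lab <- rep(as.character(1:3), each = T - fs)
      } else {
        feat <- unlist(xtr)
        lab <- rep(as.character(1:3), each = T)
      }
      model <- diag_lda_fit(matrix(feat, ncol = 1), lab)
      test_feat <- unlist(lapply(xte, function(v) v[cols]))
      truth <- rep(as.character(1:3), each = fs)
      facc[f] <- mean(diag_lda_predict(model, matrix(test_feat, ncol = 1)) ==
                        truth)
    }
    out[b] <- mean(facc)
  }
  out
}

## core entry shared by the observed path and the permutation null:
## exe_vals / obs_vals are lists of 3 per-action numeric vectors (rates of
## one bin). Returns the bootstrap accuracy vector.
accuracy_boot_values <- function(exe_vals, obs_vals, mode, n_boot = 1000,
                                 train_folds = TRUE, engine = "fast") {
  tt <- mode_tasks(mode)
  vals <- list(execution = exe_vals, observation = obs_vals)
  vtr <- vals[[tt[["train"]]]]
  vte <- vals[[tt[["test"]]]]
  T <- cv_trial_count(c(lengths(exe_vals), lengths(obs_vals)))
  if (is.na(T)) stop("fewer than 8 trials in some condition: neuron excluded from classification")
  same_task <- tt[["train"]] == tt[["test"]]
  idx_tr <- draw_boot_indices(lengths(vtr), T, n_boot)
  idx_te <- if (same_task) idx_tr else draw_boot_indices(lengths(vte), T, n_boot)
  fn <- if (identical(engine, "fast")) fast_accuracy else reference_accuracy
  fn(vtr, vte, idx_tr, idx_te, same_task, T, n_boot, train_folds)
}

#' Bootstrap classification accuracy of a single neuron in one bin
#'
#' @param recording an `mn_recording`.
#' @param bin bin index 1..24.
#' @param mode one of `"e2e"`, `"o2o"`, `"e2o"`, `"o2e"` (train task `2`
#'   test task).
#' @param n_boot bootstrap resamples (default 1000).
#' @param train_folds if `TRUE` (default) the classifier is fit on the
#'   training task's 7/8 folds; if `FALSE` on all its resampled trials.
#' @param engine `"fast"` (vectorized nearest-mean equivalent) or
#'   `"reference"` (explicit diagonal-LDA fits; identical results, slow).
#' @param seed optional seed for the resampling.
#' @param cond_rates optional precomputed [condition_rates()] for the
#'   recording.
#' @return object of class `accuracy_dist`: list with `mode`, `bin`,
#'   `accuracies` (length `n_boot`, each in `[0, 1]`), `mean`,
#'   `p_vs_chance` (fraction of resamples with accuracy at or below 1/3)
#'   and `trials_used` (T).
#' @export
classifier_accuracy <- function(recording, bin, mode, n_boot = 1000,
                                train_folds = TRUE, engine = "fast",
                                seed = NULL, cond_rates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cond_rates)) cond_rates <- condition_rates(recording)
  exe_vals <- lapply(ACTIONS, function(ac) cond_rates$execution[[ac]][, bin])
  obs_vals <- lapply(ACTIONS, function(ac) cond_rates$observation[[ac]][, bin])
  acc <- accuracy_boot_values(exe_vals, obs_vals, mode, n_boot,
                              train_folds, engine)
  structure(list(mode = mode, bin = bin, accuracies = acc,
                 mean = mean(acc),
                 p_vs_chance = mean(acc <= 1 / 3),
                 trials_used = cv_trial_count(c(lengths(exe_vals),
                                                lengths(obs_vals)))),
            class = "accuracy_dist")
}
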