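## Pseudo-population decoding: each neuron contributes one feature (its
## discharge rate in the bin under study). Neurons were not recorded
## simultaneously, so pseudo-trials are assembled per bootstrap resample by
## pairing each neuron's i-th independently sampled trial within a
## condition; noise correlations across neurons are not preserved by
## construction. Eight trials per condition are used (one per fold of the
## 8-fold cross validation).

#' Pseudo-population classification accuracy in one bin
#'
#' Per bootstrap resample each neuron independently contributes 8 sampled
#' trials per condition (with replacement); the diagonal LDA is fit on the
#' training task's 7 folds and tested on the test task's held-out fold.
#'
#' @param population an `mn_population` of screened neurons.
#' @param bin bin index 1..24.
#' @param mode `"e2e"`, `"o2o"`, `"e2o"` or `"o2e"`.
#' @param subset integer indices of the neurons to use (default all); an
#'   empty subset yields an `NA` accuracy recorded as missing.
#' @param n_boot bootstrap resamples (default 1000).
#' @param ci central interval coverage (default 0.90, the convention for the
#'   population analyses; single-neuron analyses use 0.95).
#' @param train_folds if `TRUE` (default) train on 7/8 folds, else on all 8.
#' @param var_floor pooled-variance floor per feature.
#' @param seed optional seed.
#' @param engine `"fast"` (vectorized) or `"reference"` (explicit
#'   [diag_lda_fit()] loop; identical results).
#' @param pop_rates optional precomputed [population_rates()].
#' @return object of class `population_accuracy`: list with `mode`, `bin`,
#'   `subset_size`, `accuracies`, `mean`, `ci` (central percentile
#'   interval).
#' @export
population_accuracy <- function(population, bin, mode, subset = NULL,
                                n_boot = 1000, ci = 0.90,
                                train_folds = TRUE, var_floor = 1e-9,
                                seed = NULL, engine = "fast",
                                pop_rates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop_rates)) pop_rates <- population_rates(population)
  n_all <- length(pop_rates)
  if (is.null(subset)) subset <- seq_len(n_all)
  d <- length(subset)
  if (d == 0L)
    return(structure(list(mode = mode, bin = bin, subset_size = 0L,
                          accuracies = NULL, mean = NA_real_,
                          ci = c(NA_real_, NA_real_)),
                     class = "population_accuracy"))
  tt <- mode_tasks(mode)
  same_task <- tt[["train"]] == tt[["test"]]
  T <- 8L
  ## values[[task]][[action]][[j]] = per-trial rates of subset neuron j
  values <- lapply(TASKS, function(tk) lapply(ACTIONS, function(ac)
    lapply(subset, function(i) {
      v <- pop_rates[[i]][[tk]][[ac]][, bin]
      if (length(v) < T) stop("every neuron needs >= 8 trials per condition")
      v
    })))
  names(values) <- TASKS
  for (tk in TASKS) names(values[[tk]]) <- ACTIONS
  ## sampled arrays [n_boot, 8, d] per task x action
  draw <- function(task) lapply(ACTIONS, function(ac) {
    X <- array(0, c(n_boot, T, d))
    for (j in seq_len(d)) {
      v <- values[[task]][[ac]][[j]]
      X[, , j] <- v[matrix(sample.int(length(v), n_boot * T, replace = TRUE),
                           n_boot, T)]
    }
    X
  })
  Xtr <- draw(tt[["train"]])
  Xte <- if (same_task) Xtr else draw(tt[["test"]])
  arr_sum <- function(X) Reduce(`+`, lapply(seq_len(T), function(f) X[, f, ]))
  S <- lapply(Xtr, arr_sum)                       # [n_boot, d] per class
  Q <- lapply(Xtr, function(X) arr_sum(X^2))
  n_train <- if (train_folds) T - 1L else T
  df_var <- 3L * n_train - 3L
  acc <- matrix(0, n_boot, 8L)
  for (f in 1:8) {
    mu <- lapply(1:3, function(k) {
      if (train_folds) (S[[k]] - Xtr[[k]][, f, , drop = FALSE][, 1L, ]) / n_train
      else S[[k]] / T
    })
    ## pooled within-class variance per feature over the training rows
    ss <- 0
    for (k in 1:3) {
      qk <- if (train_folds) Q[[k]] - Xtr[[k]][, f, , drop = FALSE][, 1L, ]^2
            else Q[[k]]
      ss <- ss + qk - n_train * mu[[k]]^2
    }
    v <- pmax(ss / df_var, var_floor)
    ncorrect <- numeric(n_boot)
    for (k in 1:3) {
      x <- Xte[[k]][, f, , drop = FALSE][, 1L, ]
      if (d == 1L) x <- matrix(x, n_boot, 1L)
      sc <- lapply(1:3, function(c2) {
        m <- mu[[c2]]
        if (d == 1L) m <- matrix(m, n_boot, 1L)
        rowSums((x - m)^2 / (if (d == 1L) matrix(v, n_boot, 1L) else v))
      })
      pred <- rep(1L, n_boot)
      best <- sc[[1L]]
      w <- sc[[2L]] < best; pred[w] <- 2L; best[w] <- sc[[2L]][w]
      w <- sc[[3L]] < best; pred[w] <- 3L
      ncorrect <- ncorrect + (pred == k)
    }
    acc[, f] <- ncorrect / 3
  }
  a <- rowMeans(acc)
  if (identical(engine, "reference"))
    a <- population_accuracy_reference(Xtr, Xte, same_task, train_folds,
                                       var_floor)
  lo <- (1 - ci) / 2
  structure(list(mode = mode, bin = bin, subset_size = d,
                 accuracies = a, mean = mean(a),
                 ci = unname(stats::quantile(a, c(lo, 1 - lo)))),
            class = "population_accuracy")
}

## slow path through diag_lda_fit/predict on the same sampled arrays
population_accuracy_reference <- function(Xtr, Xte, same_task, train_folds,
                                          var_floor) {
  n_boot <- dim(Xtr[[1L]])[1L]
  T <- dim(Xtr[[1L]])[2L]
  d <- dim(Xtr[[1L]])[3L]
  out <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    facc <- numeric(8)
    for (f in 1:8) {
      train_rows <- if (train_folds) setdiff(seq_len(T), f) else seq_len(T)
      feat <- do.call(rbind, lapply(1:3, function(k)
        matrix(Xtr[[k]][b, train_rows, ], length(train_rows), d)))
      lab <- rep(as.character(1:3), each = length(train_rows))
      model <- diag_lda_fit(feat, lab, var_floor = var_floor)
      test <- do.call(rbind, lapply(1:3, function(k)
        matrix(Xte[[k]][b, f, ], 1L, d)))
      facc[f] <- mean(diag_lda_predict(model, test) == as.character(1:3))
    }
    out[b] <- mean(facc)
  }
  out
}

#' Select subpopulations from shared-code labels
#'
#' @param labels a label data.frame with columns `neuron_id`, `bin`,
#'   `label` — either method labels from [shared_bin_labels()] or
#'   threshold-method labels from [threshold_labels()].
#' @param rule selection rule:
#'   * `any_shared`: neurons with at least one shared bin (global set);
#'   * `only_shared_threshold`: neurons all of whose labeled bins are
#'     shared (and that have at least one) — intended for threshold-method
#'     labels, where unlabeled bins are simply absent;
#'   * `per_bin_shared`: per action-period bin, the neurons shared in that
#'     bin (variable population size).
#' @param neuron_ids the screened population's neuron ids, used to convert
#'   ids to positional indices.
#' @return for the global rules an integer vector of neuron indices; for
#'   `per_bin_shared` a named list of index vectors, one per action-period
#'   bin.
#' @export
binwise_subpopulations <- function(labels,
                                   rule = c("any_shared",
                                            "only_shared_threshold",
                                            "per_bin_shared"),
                                   neuron_ids = sort(unique(labels$neuron_id))) {
  rule <- match.arg(rule)
  idx_of <- function(ids) sort(match(unique(ids), neuron_ids))
  if (rule == "any_shared") {
    idx_of(labels$neuron_id[labels$label == "shared"])
  } else if (rule == "only_shared_threshold") {
    per <- split(labels$label, labels$neuron_id)
    ok <- vapply(per, function(l) any(l == "shared") && all(l == "shared"), NA)
    idx_of(as.integer(names(per))[ok])
  } else {
    ap <- action_period_bins()
    out <- lapply(ap, function(b)
      idx_of(labels$neuron_id[labels$bin == b & labels$label == "shared"]))
    names(out) <- paste0("bin", ap)
    out
  }
}
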