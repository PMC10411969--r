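## Shared-code decisions per action-period bin.
##
## For each bin coding actions in BOTH tasks, three alternative criteria
## decide whether the action code is shared between execution and
## observation:
##   discharge  - per action, a bin-wise rank-sum test compares execution
##                against observation rates; shared iff no action differs
##                (after BH over all both-coding bins x 3 actions).
##   preference - bootstrap action-preference similarity indices (positive
##                and negative polarity); shared iff either index is
##                significantly equal to 1 (BH over both-coding bins x 2).
##   lda        - cross-task classification: shared iff the e2o bootstrap
##                accuracy is significantly above chance (BH over
##                both-coding bins).
##
## All three run over an arbitrary execution/observation pairing of neurons
## so the same code path serves the observed data (identity pairing) and
## the independence permutation null (derangements).

PREF_TOL <- 1e-12

#' Action-preference similarity index
#'
#' Reduces the two per-task triplets of mean discharge rates to indicator
#' vectors marking the preferred action and returns the dot product of the
#' unit-normalized indicators. With `polarity = "positive"` each vector is
#' divided by its maximum and floored, marking the highest-rate action(s);
#' with `"negative"` the maximum is subtracted, the vector divided by its
#' (signed) minimum and floored, marking the lowest-rate action(s). An index
#' of 1 means the same preference in both tasks, 0 disjoint preferences.
#'
#' @param exe_means,obs_means numeric length-3 mean rates (lift, twist,
#'   shift order is irrelevant as long as it matches).
#' @param polarity `"positive"` or `"negative"`.
#' @return index in `[0, 1]`.
#' @examples
#' preference_index(c(10, 5, 2), c(8, 3, 1))            # 1
#' preference_index(c(10, 5, 2), c(1, 9, 2))            # 0
#' preference_index(c(10, 10, 2), c(5, 1, 1))           # 1/sqrt(2)
#' preference_index(c(10, 5, 2), c(7, 6, 1), "negative") # 1
#' @export
preference_index <- function(exe_means, obs_means,
                             polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  ia <- pref_indicator(exe_means, polarity)
  ib <- pref_indicator(obs_means, polarity)
  sum(ia * ib) / sqrt(sum(ia^2) * sum(ib^2))
}

pref_indicator <- function(v, polarity) {
  if (length(v) != 3L || anyNA(v)) stop("need 3 finite mean rates")
  if (diff(range(v)) <= PREF_TOL)
    stop("undefined preference index: all three mean rates are equal ",
         "(excluded upstream by the Kruskal-Wallis gate)")
  if (polarity == "positive") {
    floor(v / max(v) + PREF_TOL)
  } else {
    w <- v - max(v)
    floor(w / min(w) + PREF_TOL)
  }
}

## vectorized bootstrap of both similarity indices for one bin.
## exe_vals/obs_vals: lists of 3 per-action rate vectors (all trials).
## Degenerate resamples with all three means equal count as "all actions
## tied", i.e. an all-ones indicator.
pref_boot_indices <- function(exe_vals, obs_vals, n_boot) {
  boot_means <- function(vals) {
    sapply(vals, function(v) {
      idx <- matrix(sample.int(length(v), n_boot * length(v), replace = TRUE),
                    n_boot, length(v))
      rowMeans(matrix(v[idx], n_boot, length(v)))
    })
  }
  Me <- boot_means(exe_vals)
  Mo <- boot_means(obs_vals)
  ind <- function(M, polarity) {
    rng <- apply(M, 1L, function(r) diff(range(r)))
    degenerate <- rng <= PREF_TOL
    I <- matrix(1, nrow(M), 3L)
    ok <- !degenerate
    if (any(ok)) {
      Mo_ <- M[ok, , drop = FALSE]
      if (polarity == "positive") {
        I[ok, ] <- floor(Mo_ / apply(Mo_, 1L, max) + PREF_TOL)
      } else {
        W <- Mo_ - apply(Mo_, 1L, max)
        I[ok, ] <- floor(W / apply(W, 1L, min) + PREF_TOL)
      }
    }
    I
  }
  idx_of <- function(polarity) {
    Ie <- ind(Me, polarity); Io <- ind(Mo, polarity)
    rowSums(Ie * Io) / sqrt(rowSums(Ie^2) * rowSums(Io^2))
  }
  list(positive = idx_of("positive"), negative = idx_of("negative"))
}

## values of one bin for one neuron, one task
bin_values <- function(cond_rates_task, bin)
  lapply(ACTIONS, function(ac) cond_rates_task[[ac]][, bin])

#' Shared-code bin labels under one method
#'
#' Labels every (neuron, action-period bin) as `shared`, `non_shared`,
#' `obs_only` or `none`. `shared`/`non_shared` can only occur where the bin
#' codes actions in both tasks; `obs_only` where it codes during observation
#' but not execution. The `pairing` argument re-pairs neuron `i`'s execution
#' data with neuron `pairing[i]`'s observation data and exists for the
#' independence permutation null; the default identity pairing gives the
#' observed-data labels.
#'
#' @param population an `mn_population` of screened neurons.
#' @param coding a [coding_flags()] table for the same population.
#' @param method `"discharge"`, `"preference"` or `"lda"`.
#' @param pairing integer permutation of the neuron indices (default
#'   identity).
#' @param n_boot bootstrap resamples for the preference and lda methods.
#' @param alpha BH level (default 0.05).
#' @param seed optional seed.
#' @param pop_rates optional precomputed [population_rates()].
#' @param train_folds passed to the lda accuracy engine.
#' @return object of class `bin_labels`: data.frame (neuron_id, bin, label,
#'   method) with attributes `n_both_bins`, `bh_family` and, for the lda
#'   method, the per-bin e2o accuracy summary.
#' @export
shared_bin_labels <- function(population, coding,
                              method = c("discharge", "preference", "lda"),
                              pairing = NULL, n_boot = 1000, alpha = 0.05,
                              seed = NULL, pop_rates = NULL,
                              train_folds = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(coding, "coding_table"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop_rates)) pop_rates <- population_rates(population)
  n <- length(pop_rates)
  if (is.null(pairing)) pairing <- seq_len(n)
  stopifnot(length(pairing) == n, all(sort(pairing) == seq_len(n)))
  ap <- action_period_bins()
  exe_f <- coding$flags$execution[, ap, drop = FALSE]
  obs_f <- coding$flags$observation[pairing, ap, drop = FALSE]
  both <- exe_f & obs_f
  pairs <- which(both, arr.ind = TRUE)  # columns: neuron row, bin col (1..12)
  K <- nrow(pairs)
  p_per_bin <- if (method == "discharge") 3L else if (method == "preference") 2L else 1L
  shared <- logical(K)
  acc_summary <- NULL
  if (K > 0L) {
    pv <- matrix(NA_real_, K, p_per_bin)
    acc_mean <- numeric(K)
    for (kk in seq_len(K)) {
      i <- pairs[kk, 1L]
      b <- ap[pairs[kk, 2L]]
      exe_vals <- bin_values(pop_rates[[i]]$execution, b)
      obs_vals <- bin_values(pop_rates[[pairing[i]]]$observation, b)
      if (method == "discharge") {
        pv[kk, ] <- vapply(1:3, function(a)
          rank_sum(exe_vals[[a]], obs_vals[[a]]), numeric(1))
      } else if (method == "preference") {
        idx <- pref_boot_indices(exe_vals, obs_vals, n_boot)
        pv[kk, 1L] <- mean(idx$positive < 1 - 1e-9)
        pv[kk, 2L] <- mean(idx$negative < 1 - 1e-9)
      } else {
        acc <- accuracy_boot_values(exe_vals, obs_vals, "e2o", n_boot,
                                    train_folds = train_folds)
        pv[kk, 1L] <- mean(acc <= 1 / 3)
        acc_mean[kk] <- mean(acc)
      }
    }
    rej <- matrix(bh_reject(as.vector(pv), alpha = alpha),
                  K, p_per_bin)
    shared <- if (method == "discharge") rowSums(rej) == 0L else
      rowSums(rej) > 0L
    if (method == "lda")
      acc_summary <- data.frame(
        neuron_id = coding$neuron_ids[pairs[, 1L]],
        bin = ap[pairs[, 2L]], e2o_mean = acc_mean, p = pv[, 1L])
  }
  labels <- matrix("none", n, length(ap))
  obs_only <- obs_f & !exe_f
  labels[obs_only] <- "obs_only"
  if (K > 0L) {
    labels[pairs] <- ifelse(shared, "shared", "non_shared")
  }
  out <- data.frame(neuron_id = rep(coding$neuron_ids, length(ap)),
                    bin = rep(ap, each = n),
                    label = as.vector(labels),
                    method = method)
  structure(out, class = c("bin_labels", "data.frame"),
            n_both_bins = K, bh_family = K * p_per_bin,
            accuracy = acc_summary, alpha = alpha)
}

#' Same-discharge shared-code labels
#'
#' Per both-coding bin, three bin-wise rank-sum tests compare the
#' action-specific discharge rates between tasks (BH family: both-coding
#' bins x 3). A bin is shared iff no action differs significantly.
#' @inheritParams shared_bin_labels
#' @return see [shared_bin_labels()].
#' @export
same_discharge <- function(population, coding, alpha = 0.05,
                           pop_rates = NULL) {
  shared_bin_labels(population, coding, method = "discharge", alpha = alpha,
                    pop_rates = pop_rates)
}

#' Same-preference shared-code labels
#'
#' Bootstraps (within the six conditions, with replacement) the positive and
#' negative action-preference similarity indices per both-coding bin; the
#' p-value is the fraction of resamples with an index below 1 (BH family:
#' both-coding bins x 2). A bin is shared iff either polarity is
#' significantly at 1.
#' @inheritParams shared_bin_labels
#' @return see [shared_bin_labels()].
#' @export
same_preference <- function(population, coding, n_boot = 1000, alpha = 0.05,
                            seed = NULL, pop_rates = NULL) {
  shared_bin_labels(population, coding, method = "preference",
                    n_boot = n_boot, alpha = alpha, seed = seed,
                    pop_rates = pop_rates)
}

#' Cross-task (LDA) shared-code labels
#'
#' Per both-coding bin, the bootstrap distribution of the e2o classifier
#' accuracy yields p = fraction of resamples at or below chance (1/3); BH
#' family: both-coding bins. A bin is shared iff significantly above chance.
#' @inheritParams shared_bin_labels
#' @return see [shared_bin_labels()]; the per-bin e2o accuracy means are in
#'   `attr(, "accuracy")`.
#' @export
cross_task_shared <- function(population, coding, n_boot = 1000,
                              alpha = 0.05, seed = NULL, pop_rates = NULL,
                              train_folds = TRUE) {
  shared_bin_labels(population, coding, method = "lda", n_boot = n_boot,
                    alpha = alpha, seed = seed, pop_rates = pop_rates,
                    train_folds = train_folds)
}

#' Summarize shared-code labels
#'
#' @param labels a `bin_labels` data.frame.
#' @param n_neurons total neurons examined (denominator for the neuron
#'   fraction); defaults to the neurons present in `labels`.
#' @return one-row data.frame with counts and denominators: shared,
#'   non_shared, obs_only bins, both-coding bins, total bins examined, and
#'   neurons with at least one shared bin.
#' @export
label_summary <- function(labels, n_neurons = length(unique(labels$neuron_id))) {
  tot <- nrow(labels)
  shared_ids <- unique(labels$neuron_id[labels$label == "shared"])
  data.frame(method = labels$method[1L],
             n_shared = sum(labels$label == "shared"),
             n_non_shared = sum(labels$label == "non_shared"),
             n_obs_only = sum(labels$label == "obs_only"),
             n_both = attr(labels, "n_both_bins"),
             n_bins = tot,
             pct_shared_of_all = 100 * sum(labels$label == "shared") / tot,
             n_neurons_shared = length(shared_ids),
             n_neurons = n_neurons,
             pct_neurons_shared = 100 * length(shared_ids) / n_neurons)
}
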