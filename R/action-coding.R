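## Per neuron x bin x task action coding.
##
## For every neuron, bin (1..24) and task, a Kruskal-Wallis test across the
## three actions asks whether the discharge rate depends on the action.
## The two tasks form two separate Benjamini-Hochberg families of size
## n_neurons x 24 each. Action-period summaries (Exe, Obs, both, Obs-only)
## are derived on bins 9-20 only.

#' Action-coding table for a population
#'
#' @param population an `mn_population` of screened neurons.
#' @param alpha BH level (default 0.05).
#' @param pop_rates optional precomputed [population_rates()].
#' @return object of class `coding_table`: list with
#'   * `table`: data.frame (neuron_id, bin, task, p, reject),
#'   * `flags`: list of two logical neuron x 24 matrices (`execution`,
#'     `observation`),
#'   * `action_period`: data.frame over bins 9-20 with `exe_coding`,
#'     `obs_coding`, `both`, `obs_only`,
#'   * `family_sizes`: named sizes of the two BH families (tests with
#'     undefined p, e.g. empty bins, are excluded and counted in
#'     `excluded_tests`).
#' @export
coding_flags <- function(population, alpha = 0.05, pop_rates = NULL) {
  stopifnot(inherits(population, "mn_population"))
  if (is.null(pop_rates)) pop_rates <- population_rates(population)
  n <- length(pop_rates)
  if (n == 0L) stop("empty population: no neurons survived screening")
  ids <- vapply(population$neurons, `[[`, 1L, "neuron_id")
  flags <- list()
  tab <- list()
  family_sizes <- c(execution = 0L, observation = 0L)
  excluded <- c(execution = 0L, observation = 0L)
  for (tk in TASKS) {
    p <- matrix(NA_real_, n, 24L)
    for (i in seq_len(n)) {
      cr <- pop_rates[[i]][[tk]]
      for (b in 1:24) {
        groups <- lapply(ACTIONS, function(ac) cr[[ac]][, b])
        if (any(lengths(groups) == 0L)) next  # undefined: no trials
        p[i, b] <- kruskal_wallis(groups)$p.value
      }
    }
    defined <- !is.na(p)
    m <- sum(defined)
    excluded[tk] <- n * 24L - m
    family_sizes[tk] <- m
    rej <- matrix(FALSE, n, 24L)
    rej[defined] <- bh_reject(p[defined], alpha = alpha, m = m)
    flags[[tk]] <- rej
    tab[[tk]] <- data.frame(neuron_id = rep(ids, 24L),
                            bin = rep(1:24, each = n),
                            task = tk,
                            p = as.vector(p),
                            reject = as.vector(rej))
  }
  ap <- action_period_bins()
  exe <- flags$execution[, ap, drop = FALSE]
  obs <- flags$observation[, ap, drop = FALSE]
  action_period <- data.frame(
    neuron_id = rep(ids, length(ap)),
    bin = rep(ap, each = n),
    exe_coding = as.vector(exe),
    obs_coding = as.vector(obs),
    both = as.vector(exe & obs),
    obs_only = as.vector(obs & !exe))
  structure(list(table = do.call(rbind, tab),
                 flags = flags,
                 action_period = action_period,
                 family_sizes = family_sizes,
                 excluded_tests = excluded,
                 alpha = alpha,
                 neuron_ids = ids),
            class = "coding_table")
}

#' @export
print.coding_table <- function(x, ...) {
  ap <- x$action_period
  cat(sprintf(
    "<coding_table> %d neurons; action-period bins: %d obs-coding (%.1f%%), %d both, %d obs-only\n",
    length(x$neuron_ids), sum(ap$obs_coding),
    100 * mean(ap$obs_coding), sum(ap$both), sum(ap$obs_only)))
  invisible(x)
}
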