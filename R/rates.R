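## Per-trial 24-bin rate matrices, grouped by condition.

#' Per-trial bin-rate matrix for one recording
#'
#' @param recording an `mn_recording`.
#' @return numeric matrix, trials x 24, of discharge rates in Hz.
#' @export
rate_matrix <- function(recording) {
  stopifnot(inherits(recording, "mn_recording"))
  n <- nrow(recording$trials)
  out <- matrix(0, n, 24L)
  for (i in seq_len(n)) {
    ev <- as.numeric(recording$trials[i, ALL_EVENTS])
    names(ev) <- ALL_EVENTS
    grid <- quartile_edges(ev)
    out[i, ] <- bin_rates(recording$spikes[[i]], grid)
  }
  out
}

## rates split by task and action:
## list$execution$lift -> matrix trials x 24, etc.
condition_rates <- function(recording, rates = NULL) {
  if (is.null(rates)) rates <- rate_matrix(recording)
  out <- list()
  for (tk in TASKS) {
    out[[tk]] <- list()
    for (ac in ACTIONS) {
      sel <- recording$trials$task == tk & recording$trials$action == ac
      out[[tk]][[ac]] <- rates[sel, , drop = FALSE]
    }
  }
  out
}

#' Precompute per-condition rate matrices for a population
#'
#' @param population an `mn_population`.
#' @return list (one element per neuron) of per-task, per-action
#'   trials x 24 rate matrices; used by all downstream stages so rates are
#'   binned exactly once.
#' @export
population_rates <- function(population) {
  stopifnot(inherits(population, "mn_population"))
  lapply(population$neurons, condition_rates)
}
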