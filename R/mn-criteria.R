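## Mirror-neuron screening.
##
## A neuron qualifies as a mirror neuron if its discharge rate is modulated
## across the five screening epochs (baseline, approach, manipulation-I,
## manipulation-II, hold) for at least one action in the execution task
## (motor response) AND for at least one action in the observation task
## (visual response). Modulation is assessed by a Friedman test with trials
## as blocks and epochs as the repeated factor, Bonferroni-corrected across
## the three actions (alpha / 3). No directionality or epoch agreement is
## required between tasks.

#' Screen one neuron against the mirror-neuron criteria
#'
#' @param recording an `mn_recording`.
#' @param alpha screening level before Bonferroni correction (default 0.05;
#'   each per-action Friedman test is evaluated at `alpha / 3`).
#' @param min_trials minimum valid trials per condition (default 8); neurons
#'   below the floor are excluded.
#' @return object of class `mn_screen`: list with logical `motor`, `visual`,
#'   `mirror`, `excluded`, `reason`, and `p_values` (task x action matrix of
#'   Friedman p-values).
#' @export
classify_neuron <- function(recording, alpha = 0.05, min_trials = 8L) {
  stopifnot(inherits(recording, "mn_recording"))
  counts <- table(recording$trials$task, recording$trials$action)
  if (!all(TASKS %in% rownames(counts)) || !all(ACTIONS %in% colnames(counts)) ||
      any(counts[TASKS, ACTIONS] < min_trials)) {
    return(structure(list(motor = NA, visual = NA, mirror = FALSE,
                          excluded = TRUE,
                          reason = sprintf("fewer than %d valid trials in some condition",
                                           min_trials),
                          p_values = NULL),
                     class = "mn_screen"))
  }
  p <- matrix(NA_real_, 2, 3, dimnames = list(TASKS, ACTIONS))
  for (tk in TASKS) for (ac in ACTIONS) {
    sel <- which(recording$trials$task == tk & recording$trials$action == ac)
    m <- t(vapply(sel, function(i) {
      ev <- as.numeric(recording$trials[i, ALL_EVENTS])
      names(ev) <- ALL_EVENTS
      window_rates(recording$spikes[[i]], epoch_windows(ev))
    }, numeric(5)))
    p[tk, ac] <- friedman(m)$p.value
  }
  thr <- alpha / 3
  motor <- any(p["execution", ] < thr)
  visual <- any(p["observation", ] < thr)
  structure(list(motor = motor, visual = visual, mirror = motor && visual,
                 excluded = FALSE, reason = NA_character_, p_values = p),
            class = "mn_screen")
}

#' Screen a population and keep the mirror neurons
#'
#' @param population an `mn_population`.
#' @param alpha,min_trials passed to [classify_neuron()].
#' @return list with `screen` (data.frame: neuron_id, motor, visual, mirror,
#'   excluded, reason) and `population` (the input restricted to mirror
#'   neurons; ground truth subset accordingly).
#' @export
screen_population <- function(population, alpha = 0.05, min_trials = 8L) {
  stopifnot(inherits(population, "mn_population"))
  screens <- lapply(population$neurons, classify_neuron,
                    alpha = alpha, min_trials = min_trials)
  df <- data.frame(
    neuron_id = vapply(population$neurons, `[[`, 1L, "neuron_id"),
    motor = vapply(screens, function(s) isTRUE(s$motor), NA),
    visual = vapply(screens, function(s) isTRUE(s$visual), NA),
    mirror = vapply(screens, function(s) isTRUE(s$mirror), NA),
    excluded = vapply(screens, `[[`, NA, "excluded"),
    reason = vapply(screens, function(s)
      if (is.na(s$reason)) "" else s$reason, ""))
  keep <- df$mirror & !df$excluded
  sub <- population
  sub$neurons <- population$neurons[keep]
  if (!is.null(population$ground_truth))
    sub$ground_truth <-
      population$ground_truth[population$ground_truth$neuron_id %in%
                                df$neuron_id[keep], , drop = FALSE]
  list(screen = df, population = sub)
}
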