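## Synthetic populations of task-modulated premotor neurons.
##
## Trials follow the paired-context design: two tasks (execution by the
## monkey, observation of a human actor) times three object manipulations
## (lift, twist, shift). Event timing is drawn per task/action from uniform
## distributions spanning the central-95% duration bounds observed for each
## inter-event epoch; spiking is inhomogeneous Poisson with a
## piecewise-constant rate per quartile bin.

TASKS <- c("execution", "observation")
ACTIONS <- c("lift", "twist", "shift")
PROFILES <- c("shared", "non_shared", "obs_only", "non_coding")
INTERVALS <- c("bpr_led", "led_rls", "rls_tch", "tch_hld", "hld_rew", "rew_wdr")

#' Default inter-event duration model
#'
#' Uniform low/high bounds (ms) per task, action and inter-event epoch,
#' spanning the central 95% of the recorded epoch durations for the monkey
#' (execution) and the human actor (observation). Only the bounds and means
#' of the real durations are known, so a uniform distribution over the
#' central-95% bounds is used as the simplest model consistent with both.
#'
#' @return data.frame with columns `task`, `action`, `interval`, `low`,
#'   `high` (ms).
#' @export
default_duration_model <- function() {
  ## rows: bpr_led, led_rls, rls_tch, tch_hld, hld_rew, rew_wdr
  b <- list(
    execution = list(
      twist = c(1197, 4728, 224, 389, 113, 219, 140, 626, 329, 804, 296, 1325),
      shift = c(1242, 5211, 231, 404, 112, 248,  59, 672, 328, 805, 316, 1380),
      lift  = c(1306, 4959, 221, 389, 108, 243, 199, 637, 329, 803, 288, 700)),
    observation = list(
      twist = c(1029, 1507, 335, 662, 203, 409,  73, 287, 329, 806, 229, 786),
      shift = c(1030, 1513, 324, 663, 213, 422,  60, 297, 328, 804, 276, 787),
      lift  = c(1029, 1510, 337, 679, 231, 461, 183, 550, 330, 804, 257, 856)))
  rows <- do.call(rbind, lapply(TASKS, function(tk) {
    do.call(rbind, lapply(ACTIONS, function(ac) {
      v <- b[[tk]][[ac]]
      data.frame(task = tk, action = ac, interval = INTERVALS,
                 low = v[seq(1, 11, by = 2)], high = v[seq(2, 12, by = 2)])
    }))
  }))
  rownames(rows) <- NULL
  rows
}

validate_duration_model <- function(model) {
  need <- c("task", "action", "interval", "low", "high")
  if (!is.data.frame(model) || !all(need %in% names(model)))
    stop("duration model must be a data.frame with columns ",
         paste(need, collapse = ", "))
  for (tk in TASKS) for (ac in ACTIONS) {
    sub <- model[model$task == tk & model$action == ac, ]
    if (!all(INTERVALS %in% sub$interval))
      stop(sprintf("duration model misses intervals for %s/%s", tk, ac))
  }
  if (any(model$low <= 0) || any(model$low >= model$high))
    stop("duration bounds must satisfy 0 < low < high")
  invisible(model)
}

#' Simulation configuration
#'
#' @param n_neurons number of neurons to simulate.
#' @param trials_per_condition valid trials per each of the 6 task x action
#'   conditions; must be >= 8.
#' @param duration_model inter-event duration bounds, see
#'   [default_duration_model()].
#' @param profile_mix named fractions over the coding profiles
#'   `shared`, `non_shared`, `obs_only`, `non_coding`; must sum to 1.
#' @param rate_base baseline firing rate (Hz) in every bin.
#' @param rate_effect action-dependent rate offset (Hz) added in the coding
#'   bins for a neuron's preferred action.
#' @param rate_modulation action-independent rate elevation (Hz) in the
#'   action-period bins of both tasks; gives every neuron the task
#'   responsiveness required by the mirror-neuron screen. Set to 0 for an
#'   unmodulated population.
#' @param coding_bins bins (1..24) in which the action dependence is
#'   planted. The default `NULL` draws, per neuron, one contiguous segment
#'   inside the action period with duration 1-6 bins (shorter durations
#'   more probable, weights 6:1) and a uniform start — emulating recordings
#'   in which action coding occupies short time segments rather than the
#'   whole action. Pass an explicit bin vector to plant the same bins in
#'   every neuron.
#' @param seed integer seed; every stochastic draw of the simulation is
#'   derived from it.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_neurons = 60,
                       trials_per_condition = 16,
                       duration_model = default_duration_model(),
                       profile_mix = c(shared = 0.2, non_shared = 0.5,
                                       obs_only = 0.1, non_coding = 0.2),
                       rate_base = 10,
                       rate_effect = 20,
                       rate_modulation = 10,
                       coding_bins = NULL,
                       seed = 1L) {
  if (trials_per_condition < 8) stop("trials_per_condition must be >= 8")
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  validate_duration_model(duration_model)
  if (!all(names(profile_mix) %in% PROFILES) || anyNA(profile_mix))
    stop("profile_mix must be named over ", paste(PROFILES, collapse = ", "))
  mix <- setNames(numeric(length(PROFILES)), PROFILES)
  mix[names(profile_mix)] <- profile_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("profile_mix fractions must sum to 1")
  if (rate_base < 0 || rate_base + min(0, rate_effect) < 0 ||
      rate_base + min(0, rate_modulation) < 0)
    stop("rates must be nonnegative")
  if (!is.null(coding_bins) && !all(coding_bins %in% 1:24))
    stop("coding_bins must lie in 1..24")
  structure(list(n_neurons = as.integer(n_neurons),
                 trials_per_condition = as.integer(trials_per_condition),
                 duration_model = duration_model,
                 profile_mix = mix,
                 rate_base = rate_base,
                 rate_effect = rate_effect,
                 rate_modulation = rate_modulation,
                 coding_bins = if (is.null(coding_bins)) NULL
                               else as.integer(coding_bins),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw one trial's event times
#'
#' Samples the six inter-event epoch durations uniformly from the duration
#' model, anchors BPR at 0, and places MOV uniformly inside the TCH-HLD
#' epoch (the duration table does not separate object-movement onset).
#'
#' @param task `"execution"` or `"observation"`.
#' @param action `"lift"`, `"twist"` or `"shift"`.
#' @param duration_model see [default_duration_model()].
#' @return named numeric vector of the 8 event times (ms), strictly
#'   increasing, `BPR = 0`.
#' @export
draw_trial_events <- function(task, action,
                              duration_model = default_duration_model()) {
  task <- match.arg(task, TASKS)
  action <- match.arg(action, ACTIONS)
  sub <- duration_model[duration_model$task == task &
                          duration_model$action == action, ]
  if (!all(INTERVALS %in% sub$interval))
    stop(sprintf("duration model misses intervals for %s/%s", task, action))
  sub <- sub[match(INTERVALS, sub$interval), ]
  if (any(sub$low <= 0) || any(sub$low > sub$high))
    stop("malformed duration spec: need 0 < low <= high")
  dur <- stats::runif(6, sub$low, sub$high)
  ev7 <- c(0, cumsum(dur))
  names(ev7) <- GRID_EVENTS
  mov <- stats::runif(1, ev7[["TCH"]], ev7[["HLD"]])
  out <- c(ev7[1:4], MOV = unname(mov), ev7[5:7])
  names(out) <- ALL_EVENTS
  out
}

## draw one contiguous coding segment in action-period coordinates
draw_coding_segment <- function() {
  dur <- sample(1:6, 1L, prob = 6:1)
  start <- sample.int(12L - dur + 1L, 1L)
  ap <- action_period_bins()
  ap[start:(start + dur - 1L)]
}

## Per-bin rate maps (Hz): list rate[[task]][[action]] -> numeric(24)
profile_rate_map <- function(profile, config, coding_bins) {
  base <- rep(config$rate_base, 24)
  mod <- base
  ap <- action_period_bins()
  mod[ap] <- mod[ap] + config$rate_modulation
  maps <- list(execution = list(), observation = list())
  for (tk in TASKS) for (ac in ACTIONS) maps[[tk]][[ac]] <- mod
  add_effect <- function(maps, task, action) {
    maps[[task]][[action]][coding_bins] <-
      maps[[task]][[action]][coding_bins] + config$rate_effect
    maps
  }
  pref_exe <- sample(ACTIONS, 1L)
  ## cyclic permutation guarantees coding in both tasks with a different
  ## preferred action
  pref_obs <- switch(profile,
                     shared = pref_exe,
                     non_shared = ACTIONS[match(pref_exe, ACTIONS) %% 3 + 1],
                     obs_only = sample(ACTIONS, 1L),
                     non_coding = NA_character_)
  if (profile %in% c("shared", "non_shared"))
    maps <- add_effect(maps, "execution", pref_exe)
  if (profile != "non_coding")
    maps <- add_effect(maps, "observation", pref_obs)
  list(maps = maps,
       pref_exe = if (profile %in% c("shared", "non_shared")) pref_exe else NA,
       pref_obs = pref_obs,
       coding_bins = if (profile == "non_coding") integer(0) else coding_bins)
}

## Poisson spikes for one trial under a piecewise-constant per-bin rate
draw_trial_spikes <- function(grid, rates_hz) {
  lambda <- rates_hz * grid$widths / 1000
  counts <- stats::rpois(24L, lambda)
  if (sum(counts) == 0L) return(numeric(0))
  spikes <- unlist(lapply(which(counts > 0L), function(b) {
    stats::runif(counts[b], grid$edges[b], grid$edges[b + 1L])
  }), use.names = FALSE)
  sort(spikes)
}

#' Simulate one neuron recording
#'
#' Generates `trials_per_condition` trials for each of the six conditions
#' with event times from the duration model and Poisson spiking under the
#' profile's action -> rate map. `shared` plants the identical map in both
#' tasks, `non_shared` a cyclically permuted map, `obs_only` an
#' action-dependent map during observation only, `non_coding` no action
#' dependence.
#'
#' @param profile one of `"shared"`, `"non_shared"`, `"obs_only"`,
#'   `"non_coding"`.
#' @param config a [sim_config()].
#' @param neuron_id integer id used in exports.
#' @return object of class `mn_recording`: list with `neuron_id`, `profile`,
#'   `pref_exe`, `pref_obs`, `trials` (data.frame with task, action and the 8
#'   event columns) and `spikes` (list of spike-time vectors).
#' @export
simulate_neuron <- function(profile, config, neuron_id = 1L) {
  profile <- match.arg(profile, PROFILES)
  stopifnot(inherits(config, "sim_config"))
  coding_bins <- if (is.null(config$coding_bins)) draw_coding_segment()
                 else config$coding_bins
  pm <- profile_rate_map(profile, config, coding_bins)
  n <- config$trials_per_condition
  conds <- expand.grid(task = TASKS, action = ACTIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(conds) * n)
  spikes <- vector("list", nrow(conds) * n)
  k <- 0L
  for (i in seq_len(nrow(conds))) {
    tk <- conds$task[i]; ac <- conds$action[i]
    rate <- pm$maps[[tk]][[ac]]
    for (tr in seq_len(n)) {
      ev <- draw_trial_events(tk, ac, config$duration_model)
      grid <- quartile_edges(ev)
      k <- k + 1L
      spikes[[k]] <- draw_trial_spikes(grid, rate)
      rows[[k]] <- data.frame(trial_id = k, task = tk, action = ac,
                              as.list(ev))
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(neuron_id = as.integer(neuron_id), profile = profile,
                 pref_exe = pm$pref_exe, pref_obs = pm$pref_obs,
                 coding_bins = pm$coding_bins,
                 trials = trials, spikes = spikes),
            class = "mn_recording")
}

#' Simulate a population with planted coding profiles
#'
#' Profile counts follow `profile_mix` rounded to whole neurons (largest
#' remainders absorb the rounding).
#'
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @return object of class `mn_population`: list with `neurons` (list of
#'   [simulate_neuron()] recordings), `ground_truth` (data.frame: neuron_id,
#'   profile, preferred actions, coded bins) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  raw <- config$profile_mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  profiles <- rep(names(counts), counts)
  neurons <- lapply(seq_len(n), function(i)
    simulate_neuron(profiles[i], config, neuron_id = i))
  gt <- data.frame(
    neuron_id = seq_len(n),
    profile = profiles,
    pref_exe = vapply(neurons, function(x) as.character(x$pref_exe), ""),
    pref_obs = vapply(neurons, function(x) as.character(x$pref_obs), ""),
    coding_bins = vapply(neurons, function(x)
      paste(x$coding_bins, collapse = ";"), ""))
  structure(list(neurons = neurons, ground_truth = gt, config = config),
            class = "mn_population")
}

#' @export
print.mn_population <- function(x, ...) {
  cat(sprintf("<mn_population> %d neurons, %d trials/condition\n",
              length(x$neurons), x$config$trials_per_condition))
  print(table(x$ground_truth$profile))
  invisible(x)
}

#' Write a population to plain-text tables
#'
#' Writes `trials.csv` (one row per trial: neuron_id, trial_id, task, action,
#' the 8 event times in ms, and the spike times as a JSON array in ms) and
#' `ground_truth.csv`.
#'
#' @param population an `mn_population`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "mn_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(population$neurons, function(nr) {
    df <- nr$trials
    df$neuron_id <- nr$neuron_id
    df$spike_times <- vapply(nr$spikes, function(s)
      as.character(jsonlite::toJSON(round(s, 3))), "")
    df[, c("neuron_id", "trial_id", "task", "action", ALL_EVENTS,
           "spike_times")]
  })
  trials_path <- file.path(dir, "trials.csv")
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(do.call(rbind, rows), trials_path, row.names = FALSE)
  utils::write.csv(population$ground_truth, gt_path, row.names = FALSE)
  invisible(c(trials = trials_path, ground_truth = gt_path))
}

#' Read a population written by [write_population()]
#'
#' @param dir directory containing `trials.csv` (and optionally
#'   `ground_truth.csv`).
#' @return an `mn_population` (with `config = NULL`; `ground_truth` only if
#'   present on disk).
#' @export
read_population <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path))
    utils::read.csv(gt_path, stringsAsFactors = FALSE) else NULL
  neurons <- lapply(split(trials, trials$neuron_id), function(df) {
    df <- df[order(df$trial_id), ]
    spikes <- lapply(df$spike_times, function(s)
      as.numeric(jsonlite::fromJSON(s)))
    structure(list(neuron_id = df$neuron_id[1L],
                   profile = if (!is.null(gt))
                     gt$profile[match(df$neuron_id[1L], gt$neuron_id)]
                   else NA_character_,
                   pref_exe = NA, pref_obs = NA,
                   trials = df[, c("trial_id", "task", "action", ALL_EVENTS)],
                   spikes = spikes),
              class = "mn_recording")
  })
  neurons <- neurons[order(vapply(neurons, `[[`, 1L, "neuron_id"))]
  names(neurons) <- NULL
  structure(list(neurons = neurons, ground_truth = gt, config = NULL),
            class = "mn_population")
}
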