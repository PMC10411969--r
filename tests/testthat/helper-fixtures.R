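# Fixture builders used across the suite. All data are generated in code.

TASKS <- c("execution", "observation")
ACTIONS <- c("lift", "twist", "shift")

# event times with equal epochs (default 400 ms each); MOV mid manipulation
fixed_events <- function(epoch_ms = 400) {
  e <- epoch_ms
  c(BPR = 0, LED = e, RLS = 2 * e, TCH = 3 * e, MOV = 3.5 * e,
    HLD = 4 * e, REW = 5 * e, WDR = 6 * e)
}

# A recording with full control over the per-task/action/bin rate map.
# rate_fn(task, action) must return 24 rates in Hz. Identical event times in
# every trial keep the bin widths constant (400/4 = 100 ms).
make_recording <- function(rate_fn, n_trials = 16, neuron_id = 1L,
                           epoch_ms = 400) {
  ev <- fixed_events(epoch_ms)
  grid <- quartile_edges(ev)
  rows <- list(); spikes <- list(); k <- 0L
  for (tk in TASKS) for (ac in ACTIONS) {
    rates <- rate_fn(tk, ac)
    for (tr in seq_len(n_trials)) {
      k <- k + 1L
      spikes[[k]] <- mirrorcode:::draw_trial_spikes(grid, rates)
      rows[[k]] <- data.frame(trial_id = k, task = tk, action = ac,
                              as.list(ev))
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  structure(list(neuron_id = as.integer(neuron_id), profile = NA_character_,
                 pref_exe = NA, pref_obs = NA, coding_bins = integer(0),
                 trials = trials, spikes = spikes),
            class = "mn_recording")
}

make_population <- function(recordings) {
  structure(list(neurons = recordings, ground_truth = NULL, config = NULL),
            class = "mn_population")
}

# one-hot action rate map: preferred action gets `hi`, others `lo`, in `bins`
tuned_map <- function(pref, bins, hi = 30, lo = 10, base = 10) {
  function(action) {
    r <- rep(base, 24)
    r[bins] <- if (action == pref) hi else lo
    r
  }
}

# neuron with planted per-task preferences; pref NA = no action dependence
tuned_recording <- function(pref_exe, pref_obs, bins = 9:20, n_trials = 16,
                            neuron_id = 1L, hi = 30, lo = 10, base = 10) {
  make_recording(function(tk, ac) {
    pref <- if (tk == "execution") pref_exe else pref_obs
    if (is.na(pref)) rep(base, 24) else tuned_map(pref, bins, hi, lo, base)(ac)
  }, n_trials = n_trials, neuron_id = neuron_id)
}

# brute-force diag-LDA oracle: per-class Gaussian log-likelihood with pooled
# per-feature variance, computed independently of the package implementation
oracle_diag_lda_predict <- function(train_x, train_lab, test_x,
                                    var_floor = 1e-9) {
  classes <- unique(train_lab)
  n <- nrow(train_x); d <- ncol(train_x)
  mus <- lapply(classes, function(cl)
    colMeans(train_x[train_lab == cl, , drop = FALSE]))
  ss <- rep(0, d)
  for (j in seq_along(classes)) {
    xc <- train_x[train_lab == classes[j], , drop = FALSE]
    ss <- ss + colSums(sweep(xc, 2, mus[[j]])^2)
  }
  v <- pmax(ss / (n - length(classes)), var_floor)
  priors <- as.numeric(table(factor(train_lab, classes))) / n
  apply(test_x, 1, function(x) {
    ll <- vapply(seq_along(classes), function(j)
      sum(stats::dnorm(x, mus[[j]], sqrt(v), log = TRUE)) + log(priors[j]),
      numeric(1))
    classes[which.max(ll)]  # which.max keeps the lowest index on ties
  })
}
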