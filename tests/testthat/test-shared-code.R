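test_that("preference index reproduces the worked examples", {
  expect_equal(preference_index(c(10, 5, 2), c(8, 3, 1)), 1)
  expect_equal(preference_index(c(10, 5, 2), c(1, 9, 2)), 0)
  expect_equal(preference_index(c(10, 10, 2), c(5, 1, 1)), 1 / sqrt(2))
  expect_equal(preference_index(c(10, 5, 2), c(7, 6, 1), "negative"), 1)
  expect_error(preference_index(c(3, 3, 3), c(1, 2, 3)), "undefined")
})

test_that("preference index is permutation-equivariant and bounded", {
  set.seed(41)
  for (i in 1:50) {
    a <- runif(3, 0, 20); b <- runif(3, 0, 20)
    perm <- sample(3)
    for (pol in c("positive", "negative")) {
      idx <- preference_index(a, b, pol)
      expect_gte(idx, 0); expect_lte(idx, 1)
      expect_equal(preference_index(a[perm], b[perm], pol), idx)
    }
    # identical floored indicators always give exactly 1
    expect_equal(preference_index(a, a), 1)
  }
})

test_that("same-discharge method separates equal from scaled discharge", {
  set.seed(42)
  # neurons 1-2: identical action->rate maps (shared); neurons 3-4: same
  # preference but execution rates doubled (non-shared by discharge)
  neurons <- list(
    tuned_recording("lift", "lift", bins = 9:20, n_trials = 64, neuron_id = 1),
    tuned_recording("twist", "twist", bins = 9:20, n_trials = 64, neuron_id = 2),
    make_recording(function(tk, ac) {
      m <- tuned_map("lift", 9:20)(ac)
      if (tk == "execution") 2 * m else m
    }, n_trials = 64, neuron_id = 3),
    make_recording(function(tk, ac) {
      m <- tuned_map("shift", 9:20)(ac)
      if (tk == "execution") 2 * m else m
    }, n_trials = 64, neuron_id = 4))
  pop <- make_population(neurons)
  ct <- coding_flags(pop)
  lab <- same_discharge(pop, ct)
  planted_shared <- lab[lab$neuron_id %in% 1:2 & lab$label != "none" &
                          lab$label != "obs_only", ]
  planted_scaled <- lab[lab$neuron_id %in% 3:4 & lab$label != "none" &
                          lab$label != "obs_only", ]
  expect_gt(mean(planted_shared$label == "shared"), 0.9)
  expect_gt(mean(planted_scaled$label == "non_shared"), 0.9)
})

test_that("same-preference method: recovery, opposite preference, scale blindness", {
  set.seed(43)
  neurons <- list(
    # same preference, rates doubled across tasks: still shared by preference
    make_recording(function(tk, ac) {
      m <- tuned_map("lift", 9:20)(ac)
      if (tk == "execution") 2 * m else m
    }, n_trials = 64, neuron_id = 1),
    # opposite preference: never shared
    tuned_recording("lift", "twist", bins = 9:20, n_trials = 64, neuron_id = 2))
  pop <- make_population(neurons)
  ct <- coding_flags(pop)
  lab <- same_preference(pop, ct, n_boot = 500, seed = 43)
  l1 <- lab[lab$neuron_id == 1 & !(lab$label %in% c("none", "obs_only")), ]
  l2 <- lab[lab$neuron_id == 2 & !(lab$label %in% c("none", "obs_only")), ]
  expect_gt(mean(l1$label == "shared"), 0.9)
  expect_equal(unique(l2$label), "non_shared")
})

test_that("fast accuracy engine equals the diagonal-LDA reference engine", {
  # variable event durations make the bin widths, and hence the rates,
  # continuous, so exact distance ties (where only the documented tie-break
  # applies) do not arise
  cfg <- sim_config(n_neurons = 2, trials_per_condition = 16,
                    coding_bins = 9:20, seed = 44)
  set.seed(44)
  nr <- simulate_neuron("non_shared", cfg)
  for (md in c("e2e", "o2o", "e2o", "o2e")) {
    f <- classifier_accuracy(nr, 14, md, n_boot = 30, seed = 100,
                             engine = "fast")
    r <- classifier_accuracy(nr, 14, md, n_boot = 30, seed = 100,
                             engine = "reference")
    expect_equal(f$accuracies, r$accuracies)
  }
  set.seed(45)
  nr2 <- simulate_neuron("non_coding", cfg, neuron_id = 2)
  for (md in c("e2o", "o2o")) {
    f <- classifier_accuracy(nr2, 10, md, n_boot = 25, seed = 7, engine = "fast")
    r <- classifier_accuracy(nr2, 10, md, n_boot = 25, seed = 7,
                             engine = "reference")
    expect_equal(f$accuracies, r$accuracies)
  }
})

test_that("classifier accuracy: separable shared neuron, chance neuron, swapped maps", {
  set.seed(45)
  # well separated rates 30/10/0 Hz in 400 ms bins (shared across tasks)
  sep <- make_recording(function(tk, ac) {
    r <- rep(0, 24)
    r[9:20] <- switch(ac, lift = 30, twist = 10, shift = 0)
    r
  }, n_trials = 64, epoch_ms = 1600)
  e2o <- classifier_accuracy(sep, 14, "e2o", n_boot = 200, seed = 1)
  o2o <- classifier_accuracy(sep, 14, "o2o", n_boot = 200, seed = 2)
  expect_gt(e2o$mean, 0.9)
  expect_gt(o2o$mean, 0.9)
  expect_lt(abs(e2o$mean - o2o$mean), 0.1)
  # non-coding neuron: every mode near chance
  set.seed(46)
  flat <- tuned_recording(NA, NA, n_trials = 16)
  for (md in c("e2e", "o2o", "e2o", "o2e")) {
    a <- classifier_accuracy(flat, 14, md, n_boot = 200, seed = 3)
    expect_lt(abs(a$mean - 1 / 3), 0.12)
  }
  # cyclically permuted action->rate maps: cross-task accuracy below chance
  set.seed(47)
  swapped <- make_recording(function(tk, ac) {
    pref <- if (tk == "execution") "lift" else "twist"
    tuned_map(pref, 9:20, hi = 40, lo = 5)(ac)
  }, n_trials = 64)
  o2e <- classifier_accuracy(swapped, 14, "o2e", n_boot = 200, seed = 4)
  expect_lt(o2e$mean, 1 / 3)
})

test_that("trial count is adjusted to a multiple of eight with a hard floor", {
  expect_equal(cv_trial_count(rep(19, 6)), 16L)
  expect_equal(cv_trial_count(c(19, 19, 19, 8, 19, 19)), 8L)
  expect_true(is.na(cv_trial_count(c(19, 19, 7, 19, 19, 19))))
  set.seed(48)
  nr <- tuned_recording("lift", "lift", n_trials = 8)
  drop <- which(nr$trials$task == "execution" & nr$trials$action == "twist")[1]
  nr$trials <- nr$trials[-drop, ]; nr$spikes <- nr$spikes[-drop]
  expect_error(classifier_accuracy(nr, 14, "e2o", n_boot = 10),
               "fewer than 8 trials")
})

test_that("bootstrap summaries are stable under trial reordering", {
  set.seed(49)
  nr <- tuned_recording("lift", "lift", bins = 9:20, n_trials = 32)
  perm <- sample(nrow(nr$trials))
  nr2 <- nr
  nr2$trials <- nr$trials[perm, ]
  nr2$spikes <- nr$spikes[perm]
  a1 <- classifier_accuracy(nr, 14, "e2o", n_boot = 400, seed = 5)
  a2 <- classifier_accuracy(nr2, 14, "e2o", n_boot = 400, seed = 5)
  # resampling is exchangeable over trials: summaries agree up to MC noise
  expect_lt(abs(a1$mean - a2$mean), 0.03)
  expect_lt(abs(a1$p_vs_chance - a2$p_vs_chance), 0.05)
})

test_that("cross-task LDA method recovers shared bins and rejects swapped maps", {
  set.seed(50)
  neurons <- list(
    tuned_recording("lift", "lift", bins = 9:20, n_trials = 64,
                    neuron_id = 1, hi = 40, lo = 5),
    tuned_recording("twist", "shift", bins = 9:20, n_trials = 64,
                    neuron_id = 2, hi = 40, lo = 5))
  pop <- make_population(neurons)
  ct <- coding_flags(pop)
  lab <- cross_task_shared(pop, ct, n_boot = 500, seed = 50)
  l1 <- lab[lab$neuron_id == 1 & !(lab$label %in% c("none", "obs_only")), ]
  l2 <- lab[lab$neuron_id == 2 & !(lab$label %in% c("none", "obs_only")), ]
  expect_gt(mean(l1$label == "shared"), 0.9)
  expect_equal(unique(l2$label), "non_shared")
})

test_that("label invariants: shared/non_shared only on both-coding bins", {
  set.seed(51)
  cfg <- sim_config(n_neurons = 10, trials_per_condition = 16, seed = 51)
  pop <- simulate_population(cfg)
  ct <- coding_flags(pop)
  lab <- same_discharge(pop, ct)
  ap <- ct$action_period
  key <- paste(ap$neuron_id, ap$bin)
  m <- match(paste(lab$neuron_id, lab$bin), key)
  expect_true(all(ap$both[m][lab$label %in% c("shared", "non_shared")]))
  expect_true(all(ap$obs_only[m][lab$label == "obs_only"]))
  expect_true(all(ap$obs_coding[m][lab$label != "none"]))
})
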