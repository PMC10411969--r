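test_that("population fast engine equals the diagonal-LDA reference engine", {
  # simulated recordings give continuous rates (variable bin widths), so
  # the two engines can only differ through an implementation defect, not
  # through floating-point distance ties
  pop <- simulate_population(sim_config(n_neurons = 5,
                                        trials_per_condition = 8,
                                        coding_bins = 9:20, seed = 91))
  rates <- population_rates(pop)
  for (md in c("e2e", "o2o", "e2o", "o2e")) {
    f <- population_accuracy(pop, 14, md, n_boot = 15, seed = 9,
                             engine = "fast", pop_rates = rates)
    r <- population_accuracy(pop, 14, md, n_boot = 15, seed = 9,
                             engine = "reference", pop_rates = rates)
    expect_equal(f$accuracies, r$accuracies)
  }
})

test_that("population decoding: shared neurons decode well, chance without coding", {
  set.seed(92)
  shared_pop <- make_population(lapply(1:20, function(i)
    tuned_recording(ACTIONS[(i %% 3) + 1], ACTIONS[(i %% 3) + 1],
                    bins = 9:20, n_trials = 16, neuron_id = i,
                    hi = 40, lo = 5)))
  for (md in c("e2e", "o2o", "e2o")) {
    pa <- population_accuracy(shared_pop, 14, md, n_boot = 100, seed = 10 + 1)
    expect_gt(pa$mean, 0.9)
  }
  set.seed(93)
  flat_pop <- make_population(lapply(1:20, function(i)
    tuned_recording(NA, NA, n_trials = 16, neuron_id = i)))
  # cross-task modes have disjoint train and test trials, so noise neurons
  # decode at chance
  for (md in c("e2o", "o2e")) {
    pa <- population_accuracy(flat_pop, 14, md, n_boot = 100, seed = 20)
    expect_lt(abs(pa$mean - 1 / 3), 0.12)
  }
  # within-task modes resample with replacement, so a test trial can also
  # appear among the training trials; with many noise features this
  # memorization inflates accuracy above chance by construction (the
  # resampling scheme is part of the contract), but stays far from the
  # planted-signal regime
  for (md in c("e2e", "o2o")) {
    pa <- population_accuracy(flat_pop, 14, md, n_boot = 100, seed = 21)
    expect_gt(pa$mean, 1 / 3 - 0.05)
    expect_lt(pa$mean, 0.7)
  }
})

test_that("population within-task accuracy beats mean single-neuron accuracy", {
  set.seed(94)
  pop <- make_population(lapply(1:12, function(i)
    tuned_recording(ACTIONS[(i %% 3) + 1], ACTIONS[(i %% 3) + 1],
                    bins = 9:20, n_trials = 16, neuron_id = i)))
  rates <- population_rates(pop)
  pa <- population_accuracy(pop, 14, "o2o", n_boot = 150, seed = 30,
                            pop_rates = rates)
  singles <- vapply(seq_len(12), function(i)
    classifier_accuracy(pop$neurons[[i]], 14, "o2o", n_boot = 150,
                        seed = 30 + i)$mean, numeric(1))
  expect_gt(pa$mean, mean(singles))
})

test_that("pseudo-trial pairing is reproducible under a fixed seed", {
  set.seed(95)
  pop <- make_population(lapply(1:6, function(i)
    tuned_recording("lift", "lift", bins = 9:20, n_trials = 8,
                    neuron_id = i)))
  a <- population_accuracy(pop, 14, "e2o", n_boot = 40, seed = 77)
  b <- population_accuracy(pop, 14, "e2o", n_boot = 40, seed = 77)
  expect_identical(a$accuracies, b$accuracies)
  expect_equal(length(a$ci), 2)
})

test_that("empty subsets are recorded as missing", {
  set.seed(96)
  pop <- make_population(lapply(1:3, function(i)
    tuned_recording("lift", "lift", n_trials = 8, neuron_id = i)))
  pa <- population_accuracy(pop, 14, "e2o", subset = integer(0), n_boot = 10)
  expect_true(is.na(pa$mean))
  expect_equal(pa$subset_size, 0L)
})

test_that("subpopulation selection rules", {
  lab <- data.frame(
    neuron_id = c(1, 1, 2, 2, 3, 3),
    bin = c(9, 10, 9, 13, 13, 14),
    label = c("shared", "non_shared", "shared", "shared", "non_shared",
              "non_shared"))
  ids <- 1:3
  any_sh <- binwise_subpopulations(lab, "any_shared", neuron_ids = ids)
  expect_equal(any_sh, c(1L, 2L))
  only_sh <- binwise_subpopulations(lab, "only_shared_threshold",
                                    neuron_ids = ids)
  expect_equal(only_sh, 2L)
  # any_shared is always a superset of only_shared_threshold
  expect_true(all(only_sh %in% any_sh))
  per_bin <- binwise_subpopulations(lab, "per_bin_shared", neuron_ids = ids)
  expect_equal(per_bin$bin9, c(1L, 2L))
  expect_equal(per_bin$bin13, 2L)
  expect_equal(per_bin$bin14, integer(0))
  # all shared -> every rule returns the full set
  lab2 <- data.frame(neuron_id = rep(1:3, each = 2),
                     bin = rep(c(9, 10), 3), label = "shared")
  expect_equal(binwise_subpopulations(lab2, "any_shared", neuron_ids = ids),
               1:3)
  expect_equal(binwise_subpopulations(lab2, "only_shared_threshold",
                                      neuron_ids = ids), 1:3)
})
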