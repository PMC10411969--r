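test_that("trial event draws respect bounds, ordering, and the printed means", {
  set.seed(1)
  model <- default_duration_model()
  # 10,000 hold->reward draws for the human actor: mean within the sanity
  # band around the printed epoch mean (566-570 ms)
  sub <- model[model$task == "observation" & model$action == "twist" &
                 model$interval == "hld_rew", ]
  draws <- runif(10000, sub$low, sub$high)
  expect_gt(mean(draws), 530)
  expect_lt(mean(draws), 600)
  for (i in 1:50) {
    ev <- draw_trial_events("observation", "twist", model)
    expect_equal(unname(ev["BPR"]), 0)
    expect_true(all(diff(ev) > 0))
    expect_true(ev["REW"] - ev["HLD"] >= sub$low &&
                  ev["REW"] - ev["HLD"] <= sub$high)
  }
})

test_that("degenerate duration spec gives exact deterministic event times", {
  model <- expand.grid(task = TASKS, action = ACTIONS,
                       interval = mirrorcode:::INTERVALS,
                       stringsAsFactors = FALSE)
  model$low <- 100; model$high <- 100
  ev <- draw_trial_events("execution", "lift", model)
  expect_equal(unname(ev[c("BPR", "LED", "RLS", "TCH", "HLD", "REW", "WDR")]),
               seq(0, 600, by = 100))
  expect_error(draw_trial_events("execution", "lift", model[1:3, ]),
               "duration model")
})

test_that("event draws are reproducible under a fixed seed", {
  set.seed(99); e1 <- draw_trial_events("execution", "twist")
  set.seed(99); e2 <- draw_trial_events("execution", "twist")
  expect_identical(e1, e2)
})

test_that("sim_config validates fractions, trial floor and rates", {
  expect_error(sim_config(trials_per_condition = 7), ">= 8")
  expect_error(sim_config(profile_mix = c(shared = 0.5, non_coding = 0.4)),
               "sum to 1")
  expect_error(sim_config(rate_base = 5, rate_effect = -10), "nonnegative")
})

test_that("planted rate maps are recovered within Poisson error", {
  cfg <- sim_config(n_neurons = 1, trials_per_condition = 64,
                    coding_bins = 9:20, rate_base = 10, rate_effect = 20,
                    rate_modulation = 0, seed = 4)
  set.seed(4)
  nr <- simulate_neuron("shared", cfg)
  cr <- mirrorcode:::condition_rates(nr)
  g <- quartile_edges(unlist(nr$trials[1, mirrorcode:::ALL_EVENTS]))
  for (tk in TASKS) for (ac in ACTIONS) {
    planted <- ifelse(ac == nr$pref_exe, 30, 10)
    for (b in c(10, 14, 18)) {
      emp <- mean(cr[[tk]][[ac]][, b])
      # conservative SE: smallest plausible bin width across trials
      widths <- vapply(seq_len(nrow(nr$trials)), function(i)
        quartile_edges(unlist(nr$trials[i, mirrorcode:::ALL_EVENTS]))$widths[b],
        numeric(1))
      se <- sqrt(planted / (mean(widths) / 1000) / 64)
      expect_lt(abs(emp - planted), 3.5 * se)
    }
  }
  # non-preferred bins outside the coding window stay at base rate
  emp_out <- mean(cr$execution[[nr$pref_exe]][, 3])
  expect_lt(abs(emp_out - 10), 5)
})

test_that("zero rate everywhere yields zero spikes", {
  cfg <- sim_config(n_neurons = 1, rate_base = 0, rate_effect = 0,
                    rate_modulation = 0, seed = 1)
  set.seed(1)
  nr <- simulate_neuron("non_coding", cfg)
  expect_true(all(lengths(nr$spikes) == 0))
})

test_that("spike counts are Poisson: variance/mean ratio near 1", {
  g <- quartile_edges(fixed_events(400))
  set.seed(8)
  counts <- replicate(1000, {
    s <- mirrorcode:::draw_trial_spikes(g, rep(20, 24))
    sum(s >= 400 & s < 800)  # fixed 400 ms window
  })
  ratio <- var(counts) / mean(counts)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("population respects profile mix, seeding, and trial counts", {
  mix <- c(shared = 0.2, non_shared = 0.5, obs_only = 0.1, non_coding = 0.2)
  cfg <- sim_config(n_neurons = 20, trials_per_condition = 8,
                    profile_mix = mix, seed = 7)
  pop <- simulate_population(cfg)
  expect_equal(unname(table(pop$ground_truth$profile)[
    c("shared", "non_shared", "obs_only", "non_coding")]),
    c(4, 10, 2, 4), ignore_attr = TRUE)
  for (nr in pop$neurons)
    expect_true(all(table(nr$trials$task, nr$trials$action) == 8))
  # all-shared mix
  cfg1 <- sim_config(n_neurons = 5, profile_mix = c(shared = 1), seed = 2)
  pop1 <- simulate_population(cfg1)
  expect_true(all(pop1$ground_truth$profile == "shared"))
  # event ordering in every generated trial
  for (nr in pop1$neurons)
    for (i in seq_len(nrow(nr$trials)))
      expect_true(all(diff(unlist(nr$trials[i, mirrorcode:::ALL_EVENTS])) > 0))
})

test_that("identical config and seed give byte-identical exports", {
  cfg <- sim_config(n_neurons = 3, trials_per_condition = 8, seed = 31)
  d1 <- file.path(tempdir(), "popA"); d2 <- file.path(tempdir(), "popB")
  write_population(simulate_population(cfg), d1)
  write_population(simulate_population(cfg), d2)
  for (f in c("trials.csv", "ground_truth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # round trip preserves trials and spikes to write precision
  pop <- simulate_population(cfg)
  back <- read_population(d1)
  expect_equal(length(back$neurons), 3)
  expect_equal(back$neurons[[2]]$trials$task, pop$neurons[[2]]$trials$task)
  expect_equal(back$neurons[[2]]$spikes[[5]],
               round(pop$neurons[[2]]$spikes[[5]], 3))
})
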