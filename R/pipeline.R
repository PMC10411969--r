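## End-to-end orchestration: simulate (or accept) a population, screen it,
## build the coding table, run the three shared-code methods and their
## permutation null, the accuracy-angle analysis with the threshold method,
## the segment statistics and the population decoding, and write
## machine-readable CSV tables plus a JSON run manifest.

#' Pipeline configuration
#'
#' All analysis constants default to the standard settings: alpha 0.05,
#' 1000 bootstrap resamples, 250 permutation resamples, o2o filtering
#' thresholds 5-15% in 1% steps, chance level 1/3, 24 bins with action
#' period 9-20.
#'
#' @param simulate a [sim_config()] describing the synthetic population, or
#'   `NULL` if `population` is given.
#' @param population an `mn_population`, or `NULL` to simulate.
#' @param out_dir output directory for tables and the manifest.
#' @param alpha significance level.
#' @param n_boot bootstrap resamples for single-neuron and population
#'   classification and the preference method.
#' @param n_boot_null reduced bootstrap resamples used inside each
#'   permutation-null re-pairing (default 200; set 1000 for the full
#'   computation).
#' @param n_perm permutation resamples for the independence null.
#' @param angle_boot bootstrap resamples for the angle-fit confidence
#'   intervals.
#' @param thresholds o2o filtering thresholds (percentage points above
#'   chance).
#' @param threshold threshold used by the threshold labeling method.
#' @param chance chance level of the 3-way classification.
#' @param seed master seed; every stochastic stage consumes a child seed
#'   derived deterministically from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), population = NULL,
                            out_dir = tempfile("mirrorcode_run_"),
                            alpha = 0.05, n_boot = 1000, n_boot_null = 200,
                            n_perm = 250, angle_boot = 1000,
                            thresholds = 5:15, threshold = 10,
                            chance = 1 / 3, seed = 1L) {
  if (is.null(simulate) && is.null(population))
    stop("either a simulation config or a population is required")
  structure(list(simulate = simulate, population = population,
                 out_dir = out_dir, alpha = alpha, n_boot = n_boot,
                 n_boot_null = n_boot_null, n_perm = n_perm,
                 angle_boot = angle_boot, thresholds = thresholds,
                 threshold = threshold, chance = chance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## deterministic child seeds below 2^31
child_seed <- function(master, k) {
  as.integer(((as.double(master %% 99991L) * 2654435761 + 97 * k) %%
                2147483629))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate/load -> mirror-neuron screen -> rate binning ->
#' action-coding table -> three shared-code methods -> single-neuron
#' classification accuracies (4 modes) -> accuracy-angle analysis with the
#' threshold method -> segment statistics -> permutation null intervals ->
#' population decoding (whole population and selected subpopulations).
#' Every reported fraction carries explicit numerator and denominator
#' columns. A JSON manifest records seeds, stage timings and counts; on a
#' stage failure the manifest lists the completed stages before the error
#' is rethrown.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mirrorcode")),
                   seed = config$seed, stages = list())
  completed <- character(0)
  res <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$completed_stages <<- completed
      write_manifest(manifest, config$out_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 2))
    completed <<- c(completed, name)
    say("[%s] done in %.1f s", name, dt)
    out
  }

  pop <- stage("simulate", {
    if (!is.null(config$population)) config$population else
      simulate_population(config$simulate)
  })
  manifest$n_neurons_input <- length(pop$neurons)

  scr <- stage("screen", screen_population(pop, alpha = config$alpha))
  mn_pop <- scr$population
  manifest$n_mirror_neurons <- length(mn_pop$neurons)
  if (length(mn_pop$neurons) == 0L) {
    manifest$stages$screen$status <- "failed"
    manifest$stages$screen$error <- "no neuron passed the mirror-neuron screen"
    manifest$completed_stages <- setdiff(completed, "screen")
    write_manifest(manifest, config$out_dir)
    stop("pipeline stage 'screen': no neuron passed the mirror-neuron screen",
         call. = FALSE)
  }
  ids <- vapply(mn_pop$neurons, `[[`, 1L, "neuron_id")

  rates <- stage("rates", population_rates(mn_pop))
  coding <- stage("coding", coding_flags(mn_pop, alpha = config$alpha,
                                         pop_rates = rates))

  labels <- stage("shared_code", {
    list(discharge = same_discharge(mn_pop, coding, alpha = config$alpha,
                                    pop_rates = rates),
         preference = same_preference(mn_pop, coding, n_boot = config$n_boot,
                                      alpha = config$alpha,
                                      seed = child_seed(config$seed, 1L),
                                      pop_rates = rates),
         lda = cross_task_shared(mn_pop, coding, n_boot = config$n_boot,
                                 alpha = config$alpha,
                                 seed = child_seed(config$seed, 2L),
                                 pop_rates = rates))
  })

  acc <- stage("single_neuron_accuracy", {
    set.seed(child_seed(config$seed, 3L))
    rows <- list()
    for (i in seq_along(mn_pop$neurons)) {
      cr <- rates[[i]]
      sizes <- c(vapply(ACTIONS, function(ac) nrow(cr$execution[[ac]]), 0L),
                 vapply(ACTIONS, function(ac) nrow(cr$observation[[ac]]), 0L))
      T <- cv_trial_count(sizes)
      if (is.na(T)) next
      for (b in 1:24) for (md in MODES) {
        a <- classifier_accuracy(mn_pop$neurons[[i]], b, md,
                                 n_boot = config$n_boot, cond_rates = cr)
        rows[[length(rows) + 1L]] <-
          data.frame(neuron_id = ids[i], bin = b, mode = md,
                     mean = a$mean, p_vs_chance = a$p_vs_chance,
                     trials_used = a$trials_used)
      }
    }
    do.call(rbind, rows)
  })

  angles <- stage("angle_analysis", {
    ap_acc <- acc[acc$bin %in% action_period_bins(), ]
    pts <- angle_points(ap_acc, chance = config$chance)
    bnd <- boundary_over_thresholds(pts, thresholds = config$thresholds,
                                    n_boot = config$angle_boot,
                                    seed = child_seed(config$seed, 4L))
    thr_lab <- threshold_labels(pts, threshold = config$threshold,
                                boundary = bnd$average_boundary)
    list(points = pts, boundary = bnd, threshold_labels = thr_lab)
  })

  segs <- stage("segments", {
    out <- list()
    for (mth in c("preference", "lda")) {
      s <- population_segments(labels[[mth]])
      out[[mth]] <- list(segments = s,
                         histogram = segment_histogram(s),
                         histogram_norm = segment_histogram(s, normalize = TRUE))
    }
    out
  })

  nulls <- stage("permutation_null", {
    out <- list()
    for (mth in c("discharge", "preference", "lda")) {
      out[[mth]] <- null_distribution(mn_pop, mth, n_perm = config$n_perm,
                                      n_boot = config$n_boot_null,
                                      alpha = config$alpha,
                                      seed = child_seed(config$seed, 5L),
                                      coding = coding, pop_rates = rates)
    }
    out
  })

  popdec <- stage("population_decoding", {
    rows <- list()
    run_subset <- function(label, subset, bins) {
      for (b in bins) for (md in MODES) {
        pa <- population_accuracy(mn_pop, b, md, subset = subset,
                                  n_boot = config$n_boot,
                                  seed = child_seed(config$seed,
                                                    100L + b * 10L +
                                                      match(md, MODES)),
                                  pop_rates = rates)
        rows[[length(rows) + 1L]] <<-
          data.frame(subset = label, bin = b, mode = md,
                     subset_size = pa$subset_size, mean = pa$mean,
                     ci_lo = pa$ci[1L], ci_hi = pa$ci[2L])
      }
    }
    ap <- action_period_bins()
    run_subset("whole", seq_along(ids), ap)
    any_shared <- binwise_subpopulations(labels$lda, "any_shared",
                                         neuron_ids = ids)
    if (length(any_shared)) run_subset("lda_any_shared", any_shared, ap)
    only_shared <- binwise_subpopulations(angles$threshold_labels,
                                          "only_shared_threshold",
                                          neuron_ids = ids)
    if (length(only_shared)) run_subset("threshold_only_shared", only_shared, ap)
    per_bin <- binwise_subpopulations(labels$lda, "per_bin_shared",
                                      neuron_ids = ids)
    for (b in ap) {
      sub <- per_bin[[paste0("bin", b)]]
      if (length(sub)) run_subset("lda_per_bin_shared", sub, b)
    }
    do.call(rbind, rows)
  })

  stage("write_tables", {
    od <- config$out_dir
    w <- function(df, name) utils::write.csv(df, file.path(od, name),
                                             row.names = FALSE)
    ## per-bin coding fractions with explicit numerator/denominator
    ap_tab <- coding$action_period
    n_mn <- length(ids)
    frac <- do.call(rbind, lapply(sort(unique(coding$table$bin)), function(b) {
      d <- coding$table[coding$table$bin == b, ]
      do.call(rbind, lapply(TASKS, function(tk) {
        dd <- d[d$task == tk, ]
        data.frame(bin = b, task = tk, n_coding = sum(dd$reject),
                   n_neurons = n_mn,
                   fraction = sum(dd$reject) / n_mn)
      }))
    }))
    w(frac, "coding_fractions.csv")
    w(do.call(rbind, lapply(labels, label_summary, n_neurons = n_mn)),
      "label_fractions.csv")
    for (mth in names(labels))
      w(as.data.frame(labels[[mth]]), sprintf("bin_labels_%s.csv", mth))
    w(acc, "single_neuron_accuracy.csv")
    w(angles$points, "angle_points.csv")
    w(angles$boundary$per_threshold, "angle_fits.csv")
    w(angles$threshold_labels, "threshold_labels.csv")
    for (mth in names(segs))
      w(segs[[mth]]$segments, sprintf("segments_%s.csv", mth))
    null_tab <- do.call(rbind, lapply(names(nulls), function(mth) {
      nd <- nulls[[mth]]
      data.frame(method = mth, n_perm = nd$n_perm,
                 mean_shared_bins = nd$mean_total,
                 ci_lo = nd$ci_total[1L], ci_hi = nd$ci_total[2L],
                 mean_shared_neurons = nd$mean_neurons,
                 neurons_ci_lo = nd$ci_neurons[1L],
                 neurons_ci_hi = nd$ci_neurons[2L])
    }))
    w(null_tab, "null_intervals.csv")
    w(popdec, "population_accuracy.csv")
    invisible(NULL)
  })

  manifest$completed_stages <- completed
  manifest$counts <- list(
    n_mirror_neurons = length(ids),
    n_bins_examined = nrow(labels$lda),
    n_both_bins = attr(labels$lda, "n_both_bins"),
    average_boundary_deg = angles$boundary$average_boundary)
  write_manifest(manifest, config$out_dir)

  invisible(list(population = pop, screen = scr$screen, mn_population = mn_pop,
                 coding = coding, labels = labels, accuracy = acc,
                 angles = angles, segments = segs, nulls = nulls,
                 population_accuracy = popdec, manifest = manifest,
                 out_dir = config$out_dir))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
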