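## Accuracy-angle analysis.
##
## For every (neuron, action-period bin) the e2o and o2o bootstrap-mean
## accuracies, expressed in percentage points relative to chance (100/3),
## form a point whose polar angle atan2(e2o_rel, o2o_rel) separates
## shared-like bins (45 deg, unity line: both classifiers equally good)
## from non-shared-like bins (0 deg: e2o at chance). The angle histogram of
## the points above an o2o filtering threshold is fit with one- and
## two-Gaussian curves; the trough between the two fitted peaks is the
## boundary angle used by the threshold labeling method.

#' Polar angle of a relative-accuracy point
#'
#' @param e2o_rel,o2o_rel accuracies minus chance, in percentage points.
#' @return angle in degrees, `atan2(e2o_rel, o2o_rel)` in (-180, 180];
#'   `NA` where both inputs are 0 (undefined direction).
#' @examples
#' accuracy_angle(30, 30)  # 45
#' accuracy_angle(0, 40)   # 0
#' @export
accuracy_angle <- function(e2o_rel, o2o_rel) {
  ang <- atan2(e2o_rel, o2o_rel) * 180 / pi
  ang[e2o_rel == 0 & o2o_rel == 0] <- NA_real_
  ang
}

#' Build the accuracy-angle point table
#'
#' @param accuracy data.frame with columns `neuron_id`, `bin`, `mode`,
#'   `mean` (bootstrap-mean accuracy in `[0, 1]`) containing modes `e2o`
#'   and `o2o` for the action-period bins.
#' @param chance chance level (default 1/3).
#' @return data.frame (`angle_points`): neuron_id, bin, e2o_rel, o2o_rel
#'   (percentage points relative to chance), angle (degrees; `NA` for the
#'   undefined origin points, which are counted in `attr(, "n_undefined")`).
#' @export
angle_points <- function(accuracy, chance = 1 / 3) {
  need <- c("neuron_id", "bin", "mode", "mean")
  stopifnot(all(need %in% names(accuracy)))
  e2o <- accuracy[accuracy$mode == "e2o", ]
  o2o <- accuracy[accuracy$mode == "o2o", ]
  key <- function(d) paste(d$neuron_id, d$bin)
  m <- match(key(e2o), key(o2o))
  stopifnot(!anyNA(m))
  out <- data.frame(neuron_id = e2o$neuron_id, bin = e2o$bin,
                    e2o_rel = 100 * (e2o$mean - chance),
                    o2o_rel = 100 * (o2o$mean[m] - chance))
  out$angle <- accuracy_angle(out$e2o_rel, out$o2o_rel)
  structure(out, n_undefined = sum(is.na(out$angle)))
}

angle_histogram <- function(angles, bin_width = 2) {
  breaks <- seq(-90, 90, by = bin_width)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE, right = FALSE)
  list(centers = h$mids, counts = h$counts)
}

gauss_k <- function(x, par, k) {
  y <- 0
  for (j in seq_len(k))
    y <- y + par[[paste0("a", j)]] *
      exp(-((x - par[[paste0("b", j)]]) / par[[paste0("c", j)]])^2)
  y
}

circular_mean_deg <- function(a) {
  atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
}

#' Fit a one- or two-Gaussian curve to the angle histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `sum_j a_j * exp(-((x - b_j)/c_j)^2)` to the histogram counts of the
#' angles of all points with `o2o_rel > threshold`. For `k = 2`, a
#' successful fit must have two distinct modes (centers >= 5 degrees apart,
#' both amplitudes positive); failures are retried with jittered initial
#' centers up to `max_retry` times. Initial guesses: `k = 1` uses the
#' maximum count, circular-mean angle and a 20-degree width; `k = 2` starts
#' the centers at the two reference lines (0 and 45 degrees) with 15-degree
#' widths and the local histogram heights as amplitudes.
#'
#' @param points an [angle_points()] data.frame.
#' @param threshold o2o filtering threshold in percentage points above
#'   chance (strict inequality).
#' @param k 1 or 2 Gaussian components.
#' @param bin_width histogram bin width in degrees (default 2).
#' @param max_retry retry budget for jittered restarts (default 50).
#' @return object of class `gaussian_fit`: list with `k`, `coef`
#'   (amplitudes/centers/widths), `adj_r2`, `residuals`, `peaks` (curve
#'   maxima, degrees), `boundary` (trough between the two peaks; `k = 2`
#'   only), `threshold`, `n_points`, `attempts`, `converged`.
#' @export
fit_angle_mixture <- function(points, threshold, k = 2, bin_width = 2,
                              max_retry = 50) {
  stopifnot(k %in% 1:2)
  sel <- !is.na(points$angle) & points$o2o_rel > threshold
  ang <- points$angle[sel]
  if (length(ang) < 30L)
    stop(sprintf("fit refused: only %d points above threshold %g (< 30)",
                 length(ang), threshold))
  h <- angle_histogram(ang, bin_width)
  x <- h$centers
  y <- h$counts
  height_near <- function(deg) max(y[abs(x - deg) <= 10], 1)
  start0 <- if (k == 1L) {
    list(a1 = max(y), b1 = circular_mean_deg(ang), c1 = 20)
  } else {
    list(a1 = height_near(0), b1 = 0, c1 = 15,
         a2 = height_near(45), b2 = 45, c2 = 15)
  }
  formula <- if (k == 1L)
    y ~ a1 * exp(-((x - b1) / c1)^2)
  else
    y ~ a1 * exp(-((x - b1) / c1)^2) + a2 * exp(-((x - b2) / c2)^2)
  dat <- data.frame(x = x, y = y)
  fit <- NULL
  attempts <- 0L
  start <- start0
  repeat {
    attempts <- attempts + 1L
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    ok <- !is.null(fit)
    if (ok && k == 2L) {
      cf <- stats::coef(fit)
      ok <- abs(cf[["b1"]] - cf[["b2"]]) >= 5 &&
        cf[["a1"]] > 0 && cf[["a2"]] > 0
    }
    if (ok || attempts > max_retry) break
    ## jitter the initial centers for the retry
    start <- start0
    start$b1 <- start0$b1 + stats::runif(1, -10, 10)
    if (k == 2L) start$b2 <- start0$b2 + stats::runif(1, -10, 10)
  }
  if (is.null(fit) || (k == 2L && !ok))
    return(structure(list(k = k, converged = FALSE, attempts = attempts,
                          threshold = threshold, n_points = length(ang)),
                     class = "gaussian_fit"))
  cf <- as.list(stats::coef(fit))
  grid <- seq(-90, 90, by = 0.1)
  curve <- gauss_k(grid, cf, k)
  res <- y - gauss_k(x, cf, k)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  p <- 3 * k
  nh <- length(y)
  adj_r2 <- 1 - (1 - r2) * (nh - 1) / (nh - p - 1)
  if (k == 1L) {
    peaks <- grid[which.max(curve)]
    boundary <- NA_real_
  } else {
    ctr <- sort(c(cf$b1, cf$b2))
    between <- grid >= ctr[1L] & grid <= ctr[2L]
    boundary <- grid[between][which.min(curve[between])]
    lower_side <- grid <= boundary
    peaks <- c(grid[lower_side][which.max(curve[lower_side])],
               grid[!lower_side][which.max(curve[!lower_side])])
  }
  structure(list(k = k, converged = TRUE, coef = cf, adj_r2 = adj_r2,
                 residuals = res, centers = x, counts = y,
                 peaks = peaks, boundary = boundary,
                 threshold = threshold, n_points = length(ang),
                 attempts = attempts),
            class = "gaussian_fit")
}

#' Boundary angle across filtering thresholds
#'
#' Fits the two-Gaussian curve at every threshold, bootstraps the full point
#' set (resample with replacement, re-filter, refit) for 95% CIs of the
#' adjusted R-squared, the two peaks and the boundary, and returns the mean
#' boundary across thresholds. Per-resample two-mode failures are counted;
#' the computation aborts if any threshold's failure rate exceeds
#' `max_fail_rate`.
#'
#' @param points an [angle_points()] data.frame (the full point set; the
#'   threshold filter is applied per resample).
#' @param thresholds filtering thresholds in percentage points (default
#'   5:15).
#' @param n_boot bootstrap resamples (default 1000).
#' @param bin_width histogram bin width (degrees).
#' @param max_fail_rate abort limit for the per-threshold two-mode failure
#'   rate (default 0.10).
#' @param seed optional seed.
#' @return list with `per_threshold` (data.frame: threshold, n_points,
#'   adj_r2, lower_peak, upper_peak, boundary, bootstrap 95% CI columns,
#'   fail_rate), `average_boundary` (mean of the original-fit boundaries),
#'   `fits` (the original `gaussian_fit`s) and `n_boot`.
#' @export
boundary_over_thresholds <- function(points, thresholds = 5:15,
                                     n_boot = 1000, bin_width = 2,
                                     max_fail_rate = 0.10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(thresholds, function(th)
    fit_angle_mixture(points, th, k = 2, bin_width = bin_width))
  bad <- !vapply(fits, `[[`, NA, "converged")
  if (any(bad))
    stop("two-Gaussian fit failed on the original sample at threshold(s) ",
         paste(thresholds[bad], collapse = ", "))
  nt <- length(thresholds)
  boot <- array(NA_real_, c(n_boot, nt, 4L),
                dimnames = list(NULL, NULL,
                                c("adj_r2", "lower_peak", "upper_peak",
                                  "boundary")))
  fails <- integer(nt)
  npts <- nrow(points)
  for (r in seq_len(n_boot)) {
    res <- points[sample.int(npts, npts, replace = TRUE), ]
    for (j in seq_len(nt)) {
      f <- tryCatch(fit_angle_mixture(res, thresholds[j], k = 2,
                                      bin_width = bin_width,
                                      max_retry = 50),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        fails[j] <- fails[j] + 1L
        next
      }
      boot[r, j, ] <- c(f$adj_r2, f$peaks[1L], f$peaks[2L], f$boundary)
    }
  }
  fail_rate <- fails / n_boot
  if (any(fail_rate > max_fail_rate))
    stop(sprintf("two-mode fit failure rate exceeded %.0f%% at threshold(s) %s",
                 100 * max_fail_rate,
                 paste(thresholds[fail_rate > max_fail_rate], collapse = ", ")))
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE)
  per <- data.frame(
    threshold = thresholds,
    n_points = vapply(fits, `[[`, 0L, "n_points"),
    adj_r2 = vapply(fits, `[[`, 0, "adj_r2"),
    lower_peak = vapply(fits, function(f) f$peaks[1L], 0),
    upper_peak = vapply(fits, function(f) f$peaks[2L], 0),
    boundary = vapply(fits, `[[`, 0, "boundary"),
    fail_rate = fail_rate)
  for (q in c("adj_r2", "lower_peak", "upper_peak", "boundary")) {
    cis <- t(vapply(seq_len(nt), function(j) ci(boot[, j, q]), numeric(2)))
    per[[paste0(q, "_lo")]] <- cis[, 1L]
    per[[paste0(q, "_hi")]] <- cis[, 2L]
  }
  list(per_threshold = per,
       average_boundary = mean(per$boundary),
       fits = fits, n_boot = n_boot)
}

#' Threshold-method bin labels
#'
#' Labels every point with `o2o_rel > threshold` as `shared` if its angle is
#' at or above the boundary angle, else `non_shared`; no single-cell
#' statistical test is involved. Points at or below the threshold are
#' excluded.
#'
#' @param points an [angle_points()] data.frame.
#' @param threshold o2o threshold in percentage points (default 10; strict
#'   inequality).
#' @param boundary boundary angle in degrees, typically the
#'   `average_boundary` from [boundary_over_thresholds()].
#' @return data.frame (neuron_id, bin, angle, label) restricted to included
#'   points.
#' @export
threshold_labels <- function(points, threshold = 10, boundary) {
  sel <- !is.na(points$angle) & points$o2o_rel > threshold
  out <- points[sel, c("neuron_id", "bin", "angle")]
  out$label <- ifelse(out$angle >= boundary, "shared", "non_shared")
  rownames(out) <- NULL
  out
}
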