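# planted two-cluster angle points used by several blocks
mixture_points <- function(n = 1500, centers = c(2, 45), sd = 8,
                           w = c(0.6, 0.4), r_range = c(20, 50)) {
  comp <- sample(1:2, n, TRUE, prob = w)
  ang <- rnorm(n, centers[comp], sd)
  r <- runif(n, r_range[1], r_range[2])
  pts <- data.frame(neuron_id = rep(seq_len(ceiling(n / 12)), each = 12)[1:n],
                    bin = rep(9:20, length.out = n),
                    e2o_rel = r * sin(ang * pi / 180),
                    o2o_rel = r * cos(ang * pi / 180))
  pts$angle <- accuracy_angle(pts$e2o_rel, pts$o2o_rel)
  pts
}

test_that("accuracy angle: reference lines, undefined origin, scale invariance", {
  expect_equal(accuracy_angle(30, 30), 45)
  expect_equal(accuracy_angle(0, 40), 0)
  expect_equal(accuracy_angle(-10, 10), -45)
  expect_true(is.na(accuracy_angle(0, 0)))
  set.seed(71)
  for (i in 1:20) {
    e <- runif(1, -20, 40); o <- runif(1, -20, 40); c_ <- runif(1, 0.1, 9)
    if (e == 0 && o == 0) next
    expect_equal(accuracy_angle(c_ * e, c_ * o), accuracy_angle(e, o))
  }
})

test_that("angle point table pairs e2o with o2o and counts undefined points", {
  acc <- data.frame(neuron_id = rep(1:2, each = 4),
                    bin = rep(c(9, 10), 4),
                    mode = rep(c("e2o", "e2o", "o2o", "o2o"), 2),
                    mean = c(0.5, 1 / 3, 0.6, 1 / 3, 0.4, 0.5, 0.5, 0.6))
  pts <- angle_points(acc)
  expect_equal(nrow(pts), 4)
  expect_equal(pts$e2o_rel[1], 100 * (0.5 - 1 / 3))
  expect_equal(attr(pts, "n_undefined"), 1L)  # neuron 1 bin 10 is (0, 0)
})

test_that("noise-free two-Gaussian histogram is fit with adjR2 near 1", {
  # build angles whose histogram equals a two-Gaussian evaluation (up to
  # integer rounding)
  centers <- seq(-89, 89, by = 2)
  counts <- round(80 * exp(-((centers - 2) / 10)^2) +
                    50 * exp(-((centers - 45) / 10)^2))
  ang <- rep(centers, counts)
  pts <- data.frame(neuron_id = 1L, bin = 9L,
                    e2o_rel = 30 * sin(ang * pi / 180),
                    o2o_rel = 30 * cos(ang * pi / 180))
  pts$angle <- ang
  f <- fit_angle_mixture(pts, threshold = 5, k = 2)
  expect_true(f$converged)
  expect_gt(f$adj_r2, 0.995)
  expect_lt(max(abs(f$residuals)), 2)
  expect_equal(f$peaks, c(2, 45), tolerance = 0.05)
  expect_gt(f$boundary, 2); expect_lt(f$boundary, 45)
})

test_that("mixture recovery: two-Gaussian beats one-Gaussian on clustered angles", {
  set.seed(72)
  pts <- mixture_points(2000)
  f1 <- fit_angle_mixture(pts, 10, k = 1)
  f2 <- fit_angle_mixture(pts, 10, k = 2)
  expect_gt(f2$adj_r2, f1$adj_r2 + 0.02)
  expect_lt(abs(f2$peaks[1] - 2), 4)
  expect_lt(abs(f2$peaks[2] - 45), 4)
  # single-cluster angles: the two-Gaussian fit adds almost nothing
  set.seed(73)
  one <- mixture_points(2000, centers = c(10, 10), w = c(1, 0))
  g1 <- fit_angle_mixture(one, 10, k = 1)
  expect_lt(abs(g1$coef$b1 - 10), 2)
  g2 <- tryCatch(fit_angle_mixture(one, 10, k = 2), error = function(e) NULL)
  if (!is.null(g2) && g2$converged)
    expect_lt(g2$adj_r2 - g1$adj_r2, 0.02)
})

test_that("fit is refused below 30 points and filtering is monotone", {
  set.seed(74)
  pts <- mixture_points(300, r_range = c(6, 20))
  expect_error(fit_angle_mixture(pts, threshold = 25, k = 1), "fit refused")
  n_above <- vapply(5:15, function(th) sum(pts$o2o_rel > th), numeric(1))
  expect_true(all(diff(n_above) <= 0))
})

test_that("boundary across thresholds lies between the planted centers", {
  set.seed(75)
  pts <- mixture_points(1500)
  b <- boundary_over_thresholds(pts, thresholds = 5:15, n_boot = 30, seed = 75)
  expect_equal(nrow(b$per_threshold), 11)
  expect_true(all(b$per_threshold$boundary > 2 &
                    b$per_threshold$boundary < 45))
  expect_gt(b$average_boundary, 2)
  expect_lt(b$average_boundary, 45)
  expect_true(all(b$per_threshold$fail_rate <= 0.1))
  # bootstrap CIs bracket the point estimates
  expect_true(all(b$per_threshold$boundary_lo <= b$per_threshold$boundary &
                    b$per_threshold$boundary <= b$per_threshold$boundary_hi))
})

test_that("boundary is insensitive to the histogram bin width (1-5 degrees)", {
  set.seed(76)
  pts <- mixture_points(2000)
  bounds <- vapply(c(1, 2, 3, 4, 5), function(bw)
    fit_angle_mixture(pts, 10, k = 2, bin_width = bw)$boundary, numeric(1))
  expect_lt(max(bounds) - min(bounds), 3)
})

test_that("threshold labels follow the boundary rule and strict threshold", {
  pts <- data.frame(neuron_id = 1:4, bin = 9:12,
                    e2o_rel = c(20, 2, 15, 5),
                    o2o_rel = c(20, 20, 15, 10))
  pts$angle <- accuracy_angle(pts$e2o_rel, pts$o2o_rel)
  lab <- threshold_labels(pts, threshold = 10, boundary = 25)
  expect_equal(lab$label[lab$neuron_id == 1], "shared")      # 45 >= 25
  expect_equal(lab$label[lab$neuron_id == 2], "non_shared")  # ~5.7 < 25
  # o2o_rel == threshold exactly is excluded (strict inequality)
  expect_false(4 %in% lab$neuron_id)
  expect_equal(nrow(lab), 3)
})
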