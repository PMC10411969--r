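#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H statistic with a chi-square approximation
#' (`k - 1` degrees of freedom). Used throughout the pipeline to decide, per
#' neuron and time bin, whether the discharge rate depends on the action.
#'
#' When every observation is identical the statistic is defined as 0 and the
#' p-value as 1 (the tie-correction denominator vanishes).
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return list with elements `statistic` (H) and `p.value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("NA values are not allowed")
  N <- length(x)
  r <- rank(x)
  g <- rep.int(seq_along(groups), n_i)
  R_i <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  ## tie correction
  t <- table(x)
  correction <- 1 - sum(t^3 - t) / (N^3 - N)
  if (correction <= 0) {
    H <- 0
  } else {
    H <- H / correction
  }
  H <- max(H, 0)
  df <- length(groups) - 1L
  p <- if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  list(statistic = H, p.value = p)
}

#' Friedman rank test for repeated measures
#'
#' Within-row (midrank) Friedman chi-square with tie correction, used by the
#' mirror-neuron screen with trials as blocks and the five task epochs as the
#' repeated factor.
#'
#' @param block_matrix numeric matrix, rows = blocks (trials), columns =
#'   treatments (epochs); at least 2 of each.
#' @return list with elements `statistic` (chi-square) and `p.value`
#'   (`k - 1` df).
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 5, 9))
#' friedman(m)  # every row ordered identically -> chi2 = 6
#' @export
friedman <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L)
    stop("block_matrix must be numeric with >= 2 rows and >= 2 columns")
  if (anyNA(m)) stop("NA values are not allowed")
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1L, rank))           # midranks within each block
  R_j <- colSums(r)
  ## tie-corrected form: (k-1) * sum((R_j - n(k+1)/2)^2) / (sum(r^2) - n k (k+1)^2 / 4)
  num <- (k - 1) * sum((R_j - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  chi2 <- if (den <= 0) 0 else num / den
  p <- if (chi2 == 0) 1 else stats::pchisq(chi2, k - 1L, lower.tail = FALSE)
  list(statistic = chi2, p.value = p)
}

#' Two-sided Wilcoxon rank-sum test (normal approximation)
#'
#' Rank-sum p-value from the normal approximation with midrank tie correction
#' and a 0.5 continuity correction, i.e. the large-sample variant of the
#' two-sample Wilcoxon test. Used bin-wise by the same-discharge criterion to
#' compare execution against observation trials per action.
#'
#' @param a,b nonempty numeric vectors.
#' @return two-sided p-value.
#' @examples
#' rank_sum(c(1, 2, 3, 4), c(10, 11, 12, 13))
#' @export
rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  x <- c(a, b)
  if (anyNA(x)) stop("NA values are not allowed")
  n_a <- length(a)
  n_b <- length(b)
  N <- n_a + n_b
  r <- rank(x)
  W <- sum(r[seq_len(n_a)])
  mu <- n_a * (N + 1) / 2
  t <- table(x)
  sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  if (W == mu) z <- 0
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up rejection
#'
#' Standard BH step-up procedure at level `alpha` with an explicit family size
#' `m`, so callers can state the full test family (for example all
#' neurons x bins tests of one task) even when a few tests were undefined and
#' are not part of `pvals`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @param m family size; must be at least `length(pvals)` (default).
#' @return logical vector of rejection flags, aligned with `pvals`.
#' @examples
#' bh_reject(c(0.001, 0.02, 0.04), alpha = 0.05)
#' @export
bh_reject <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (length(pvals) == 0L) return(logical(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvals)) stop("family size m must be >= length(pvals)")
  if (alpha <= 0) return(rep(FALSE, length(pvals)))
  o <- order(pvals)
  ps <- pvals[o]
  ok <- ps <= seq_along(ps) * alpha / m
  reject <- logical(length(pvals))
  if (any(ok)) {
    kmax <- max(which(ok))
    reject[o[seq_len(kmax)]] <- TRUE
  }
  reject
}

#' Fit a diagonal linear discriminant classifier
#'
#' Gaussian classes with class-specific means and a single pooled,
#' per-feature (diagonal) within-class variance. Priors are taken from the
#' training class frequencies. Features with zero pooled variance are floored
#' at `var_floor` so silent bins cannot produce degenerate densities.
#'
#' @param features numeric matrix (trials x features) or vector (1 feature).
#' @param labels class labels, one per row of `features`.
#' @param var_floor minimum pooled variance per feature (default `1e-9`).
#' @return object of class `diag_lda` with `classes`, `means`
#'   (class x feature), `pooled_var`, `priors`.
#' @seealso [diag_lda_predict()]
#' @export
diag_lda_fit <- function(features, labels, var_floor = 1e-9) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("one label per row required")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need >= 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) stop("need >= 2 training trials per class")
  d <- ncol(x)
  means <- matrix(0, length(classes), d,
                  dimnames = list(classes, colnames(x)))
  ss <- numeric(d)
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xc)
    means[cl, ] <- mu
    ss <- ss + colSums((xc - rep(mu, each = nrow(xc)))^2)
  }
  pooled <- ss / (nrow(x) - length(classes))
  pooled <- pmax(pooled, var_floor)
  structure(
    list(classes = classes, means = means, pooled_var = pooled,
         priors = as.numeric(counts) / nrow(x), var_floor = var_floor),
    class = "diag_lda")
}

#' Predict classes from a diagonal LDA model
#'
#' Argmax over classes of the Gaussian log-density with the model's diagonal
#' pooled covariance plus the log prior. Ties go to the earliest class in the
#' model's class order.
#'
#' @param model a `diag_lda` model from [diag_lda_fit()].
#' @param features numeric matrix (or vector for a single-feature model) of
#'   test trials.
#' @return character vector of predicted class labels.
#' @export
diag_lda_predict <- function(model, features) {
  stopifnot(inherits(model, "diag_lda"))
  x <- as.matrix(features)
  d <- ncol(model$means)
  if (ncol(x) != d) {
    if (d == 1L && nrow(x) == 1L) x <- t(x) else
      stop("feature dimension mismatch")
  }
  k <- length(model$classes)
  scores <- matrix(0, nrow(x), k)
  inv2v <- 1 / (2 * model$pooled_var)
  for (j in seq_len(k)) {
    diff2 <- (x - rep(model$means[j, ], each = nrow(x)))^2
    scores[, j] <- -drop(diff2 %*% inv2v) + log(model$priors[j])
  }
  ## max.col(ties.method = "first") implements the lowest-index tie-break
  model$classes[max.col(scores, ties.method = "first")]
}
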