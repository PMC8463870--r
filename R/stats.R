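# Statistical suite for per-image EV counts and channel intensities.
# All resampling p-values use the add-one Monte-Carlo estimator
# p = (1 + #{stat* >= stat_obs}) / (n_resamples + 1), so p is never
# exactly zero and is bounded below by 1 / (n_resamples + 1).

#' Construct a test result
#'
#' Container for every hypothesis test in the package.
#'
#' @param statistic_name One of `"D_KS"`, `"T_density"`, `"D_Cov"`,
#'   `"chi2"`, `"r"`.
#' @param statistic Observed statistic value.
#' @param p_value P value in (0, 1].
#' @param n_resamples Number of resamples (`NA` for exact tests).
#' @param seed Seed used for resampling (`NA` for exact tests).
#' @param sample_sizes Integer vector of group sizes.
#' @param extra Optional named list of ancillary values (df, flags, ...).
#' @return An object of class `ev_test`.
#' @export
test_result <- function(statistic_name, statistic, p_value, n_resamples = NA_integer_,
                        seed = NA_integer_, sample_sizes = integer(0), extra = list()) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(statistic_name = statistic_name,
                 statistic = statistic,
                 p_value = p_value,
                 n_resamples = n_resamples,
                 seed = seed,
                 sample_sizes = sample_sizes,
                 extra = extra),
            class = "ev_test")
}

#' @export
print.ev_test <- function(x, ...) {
  cat(sprintf("<ev_test> %s = %.6g, p = %.4g (n = %s%s)\n",
              x$statistic_name, x$statistic, x$p_value,
              paste(x$sample_sizes, collapse = "/"),
              if (!is.na(x$n_resamples))
                sprintf(", %d resamples, seed %s", x$n_resamples, x$seed) else ""))
  invisible(x)
}

check_sample <- function(x, field) {
  if (!is.numeric(x) || !length(x) || anyNA(x))
    stop_field(field, "must be a nonempty numeric vector without NA")
  as.numeric(x)
}

#' Relative frequency distribution of per-image counts
#'
#' @param values Nonnegative integer counts (EVs per image for one
#'   condition).
#' @param max_value Upper end of the tabulated support (default: observed
#'   maximum).
#' @return List of class `ev_freq`: `frequencies` (named, over
#'   `0:max_value`, summing to 1), `median`, `zero_fraction`, `n`.
#' @examples
#' frequency_distribution(c(0, 1, 2, 3, 4))$frequencies
#' @export
frequency_distribution <- function(values, max_value = NULL) {
  values <- check_sample(values, "values")
  if (any(values < 0) || any(values != round(values)))
    stop_field("values", "must be nonnegative integers")
  if (is.null(max_value)) max_value <- max(values)
  freq <- vapply(0:max_value, function(v) mean(values == v), numeric(1L))
  names(freq) <- 0:max_value
  structure(list(frequencies = freq,
                 median = median(values),
                 zero_fraction = mean(values == 0),
                 n = length(values)),
            class = "ev_freq")
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \sup_t |F_x(t) - F_y(t)|} evaluated on the pooled support,
#' which is correct in the presence of ties (discrete counts).
#'
#' @param x,y Nonempty numeric samples.
#' @return D in \[0, 1\].
#' @examples
#' ks_statistic(c(1, 2, 3), c(10, 11, 12))  # disjoint supports: 1
#' @export
ks_statistic <- function(x, y) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  s <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(s) - ecdf(y)(s)))
}

# Vectorized bootstrap D statistics: draws n_b pooled resamples of sizes
# (nx, ny) and evaluates D on the pooled support.
boot_ks_stats <- function(pool, nx, ny, n_b) {
  s <- sort(unique(pool))
  X <- matrix(sample(pool, nx * n_b, replace = TRUE), nx, n_b)
  Y <- matrix(sample(pool, ny * n_b, replace = TRUE), ny, n_b)
  d <- matrix(0, length(s), n_b)
  for (k in seq_along(s))
    d[k, ] <- abs(colMeans(X <= s[k]) - colMeans(Y <= s[k]))
  apply(d, 2, max)
}

#' Bootstrap-corrected two-sample KS test for discrete counts
#'
#' The classical KS test assumes continuous distributions and is
#' conservative with ties. This test draws the null distribution of D by
#' pooled bootstrap: `n_b` times, resample `|x|` and `|y|` values with
#' replacement from the pooled sample and recompute D. The p-value uses the
#' add-one estimator.
#'
#' @param x,y Nonempty numeric samples (typically per-image counts).
#' @param n_b Number of bootstrap resamples (>= 1; default 10000).
#' @param seed Integer seed for the resampling.
#' @return An [test_result()] with `statistic_name = "D_KS"`.
#' @examples
#' set.seed(1)
#' ks_bootstrap_pvalue(rpois(50, 3), rpois(50, 8), n_b = 500, seed = 2)
#' @export
ks_bootstrap_pvalue <- function(x, y, n_b = 10000, seed = 1) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  n_b <- as.integer(check_number(n_b, "n_b", 1))
  d_obs <- ks_statistic(x, y)
  pool <- c(x, y)
  d_star <- withr::with_seed(seed,
                             boot_ks_stats(pool, length(x), length(y), n_b))
  p <- (1 + sum(d_star >= d_obs - 1e-12)) / (n_b + 1)
  test_result("D_KS", d_obs, p, n_b, seed, c(length(x), length(y)))
}

#' Permutation test of density equality
#'
#' Approximates both samples by Gaussian kernel density estimates with a
#' common bandwidth (Silverman's rule on the pooled sample) on a common
#' grid, and uses the integrated squared difference between the two
#' estimates as the statistic. The null is generated by permuting the group
#' labels; the p-value uses the add-one estimator.
#'
#' @param x,y Nonempty numeric samples.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param grid_n Number of grid points for the density evaluation.
#' @return An [test_result()] with `statistic_name = "T_density"`. A pooled
#'   sample with zero variance is degenerate: the test returns `p = 1` with
#'   a warning.
#' @examples
#' set.seed(1)
#' permutation_density_test(rnorm(40), rnorm(40, 3), n_perm = 199, seed = 2)
#' @export
permutation_density_test <- function(x, y, n_perm = 10000, seed = 1, grid_n = 256) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  n_perm <- as.integer(check_number(n_perm, "n_perm", 1))
  pool <- c(x, y); nx <- length(x)
  if (var(pool) == 0) {
    warning("zero pooled variance; density-equality test is degenerate")
    return(test_result("T_density", 0, 1, n_perm, seed, c(nx, length(y))))
  }
  h <- bw.nrd0(pool)
  lo <- min(pool) - 3 * h; hi <- max(pool) + 3 * h
  dx <- (hi - lo) / (grid_n - 1)
  ise <- function(a, b) {
    fa <- density(a, bw = h, from = lo, to = hi, n = grid_n)$y
    fb <- density(b, bw = h, from = lo, to = hi, n = grid_n)$y
    sum((fa - fb)^2) * dx
  }
  t_obs <- ise(x, y)
  t_star <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    idx <- sample(length(pool), nx)
    ise(pool[idx], pool[-idx])
  }, numeric(1L)))
  p <- (1 + sum(t_star >= t_obs - 1e-15)) / (n_perm + 1)
  test_result("T_density", t_obs, p, n_perm, seed, c(nx, length(y)),
              extra = list(bandwidth = h))
}

# Double-centered pairwise distance matrix.
dcov_center <- function(v) {
  a <- as.matrix(dist(v))
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

#' Sample distance covariance statistic
#'
#' Squared sample distance covariance via double-centered pairwise distance
#' matrices, \eqn{V^2_n = n^{-2} \sum_{ij} A_{ij} B_{ij}}, reported on the
#' scale \eqn{n V^2_n} (the conventional test-statistic scaling, documented
#' here because printed values are only comparable within one scaling
#' convention).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return Nonnegative statistic; exactly 0 when either argument is
#'   constant.
#' @examples
#' distance_covariance(1:10, (1:10)^2) > 0
#' distance_covariance(rep(1, 10), rnorm(10))  # 0
#' @export
distance_covariance <- function(x, y) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  if (length(x) != length(y))
    stop_field("x/y", sprintf("lengths differ (%d vs %d)", length(x), length(y)))
  n <- length(x)
  if (n < 2) stop_field("x/y", "need at least 2 paired observations")
  v2 <- max(mean(dcov_center(x) * dcov_center(y)), 0)
  n * v2
}

#' Bootstrap test of independence via distance covariance
#'
#' The null distribution is generated by resampling one margin (`y`)
#' independently with replacement, which breaks the pairing while keeping
#' the marginal distribution; a label-permutation null is available as a
#' sensitivity check. The p-value uses the add-one estimator.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param n_b Number of resamples (default 10000).
#' @param seed Integer seed.
#' @param method `"bootstrap"` (default) or `"permutation"`.
#' @return An [test_result()] with `statistic_name = "D_Cov"`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' dcov_bootstrap_test(x, x, n_b = 199, seed = 2)$p_value  # dependent: small
#' @export
dcov_bootstrap_test <- function(x, y, n_b = 10000, seed = 1,
                                method = c("bootstrap", "permutation")) {
  method <- match.arg(method)
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  if (length(x) != length(y) || length(x) < 4)
    stop_field("x/y", "need equal lengths of at least 4")
  n_b <- as.integer(check_number(n_b, "n_b", 1))
  n <- length(x)
  A <- dcov_center(x)
  stat_obs <- n * max(mean(A * dcov_center(y)), 0)
  stat_star <- withr::with_seed(seed, vapply(seq_len(n_b), function(b) {
    ys <- if (method == "bootstrap") sample(y, n, replace = TRUE) else sample(y)
    n * max(mean(A * dcov_center(ys)), 0)
  }, numeric(1L)))
  p <- (1 + sum(stat_star >= stat_obs - 1e-12)) / (n_b + 1)
  test_result("D_Cov", stat_obs, p, n_b, seed, c(n, n),
              extra = list(method = method))
}

#' Pearson correlation matrix across fluorescence channels
#'
#' Pairwise Pearson correlation of per-EV channel intensities (complete
#' rows, see [ev_intensity_table()]), with two-sided p-values from
#' [stats::cor.test()]. A zero-variance channel yields `NA` entries, which
#' are reported as missing rather than imputed.
#'
#' @param intensity_table Numeric matrix, one row per EV, one column per
#'   channel; at least 3 rows.
#' @return List with `r` (symmetric, unit diagonal), `p` (off-diagonal
#'   two-sided p-values) and `n` (number of EVs).
#' @examples
#' m <- matrix(rnorm(300), ncol = 3)
#' round(pearson_matrix(m)$r, 2)
#' @export
pearson_matrix <- function(intensity_table) {
  m <- as.matrix(intensity_table)
  if (nrow(m) < 3) stop_field("intensity_table", "need at least 3 EVs")
  if (anyNA(m)) stop_field("intensity_table", "must be complete (no NA)")
  k <- ncol(m)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(m[, i], m[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(m))
}

#' Chi-squared homogeneity test of two population compositions
#'
#' Two-sample chi-squared test on the 2 x 15 contingency table of
#' per-population EV counts, without continuity correction. Populations
#' whose expected count under homogeneity falls below `min_expected` in
#' either row are pooled into a single rest class before testing.
#'
#' @param counts_a,counts_b Numeric vectors of per-population totals
#'   (length 15, or any common length for generalized panels).
#' @param min_expected Pooling threshold for expected counts (default 5).
#' @return An [test_result()] with `statistic_name = "chi2"`; `extra`
#'   carries `df` and the number of classes kept.
#' @examples
#' chisq_population_test(c(10, 20), c(20, 10))$statistic  # 20/3
#' @export
chisq_population_test <- function(counts_a, counts_b, min_expected = 5) {
  counts_a <- check_sample(counts_a, "counts_a")
  counts_b <- check_sample(counts_b, "counts_b")
  if (length(counts_a) != length(counts_b))
    stop_field("counts_a/counts_b", "must have the same length")
  if (sum(counts_a) <= 0 || sum(counts_b) <= 0)
    stop_field("counts_a/counts_b", "totals must be > 0")
  tab <- rbind(counts_a, counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pool <- apply(expected < min_expected, 2, any)
  if (any(pool)) {
    kept <- tab[, !pool, drop = FALSE]
    tab <- cbind(kept, pooled = rowSums(tab[, pool, drop = FALSE]))
  }
  if (ncol(tab) < 2)
    stop_field("counts", "fewer than 2 classes remain after pooling")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  test_result("chi2", unname(ht$statistic), max(ht$p.value, .Machine$double.xmin),
              sample_sizes = round(rowSums(tab)),
              extra = list(df = unname(ht$parameter), classes_kept = ncol(tab)))
}

#' Ratio of sample medians
#'
#' The median is used as the measure of central tendency for per-image EV
#' counts; this reports `median(x) / median(y)`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `ratio`, `median_x`, `median_y` and `degenerate`
#'   (`TRUE` with `ratio = Inf` when `median(y)` is 0 but `median(x)` is
#'   not; 0/0 gives `NaN`).
#' @examples
#' median_fold(c(3, 3, 3), c(1, 1, 1))$ratio
#' @export
median_fold <- function(x, y) {
  x <- check_sample(x, "x"); y <- check_sample(y, "y")
  mx <- median(x); my <- median(y)
  degenerate <- my == 0
  if (degenerate)
    warning("median of the reference sample is 0; ratio is not finite")
  list(ratio = mx / my, median_x = mx, median_y = my, degenerate = degenerate)
}
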