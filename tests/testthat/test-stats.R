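test_that("frequency distributions report mass, median and zero fraction", {
  fd <- frequency_distribution(rep(0, 12))
  expect_equal(fd$zero_fraction, 1)
  expect_equal(fd$median, 0)

  fd <- frequency_distribution(0:4)
  expect_true(all(fd$frequencies == 0.2))
  expect_equal(fd$median, 2)
  expect_equal(sum(fd$frequencies), 1)
  expect_error(frequency_distribution(numeric(0)), "nonempty")
  expect_error(frequency_distribution(c(1.5, 2)), "integers")
})

test_that("the KS statistic handles ties, symmetry and monotone relabeling", {
  expect_equal(ks_statistic(c(1, 1, 2, 3), c(1, 1, 2, 3)), 0)
  expect_equal(ks_statistic(0:4, 10:14), 1)
  withr::with_seed(61, {
    for (case in 1:50) {
      x <- sample(0:10, sample(3:20, 1), replace = TRUE)
      y <- sample(0:10, sample(3:20, 1), replace = TRUE)
      d <- ks_statistic(x, y)
      expect_equal(d, ks_statistic(y, x))
      expect_equal(d, ks_oracle(x, y))
      # strictly monotone relabeling of the common support
      expect_equal(d, ks_statistic(x^2 + 3 * x, y^2 + 3 * y))
      expect_gte(d, 0); expect_lte(d, 1)
    }
  })
})

test_that("the bootstrap KS test is deterministic, floored and powerful", {
  const <- rep(4, 20)
  res <- ks_bootstrap_pvalue(const, const, n_b = 200, seed = 7)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  x <- withr::with_seed(62, rpois(100, 3))
  y <- withr::with_seed(63, rpois(100, 8))
  r1 <- ks_bootstrap_pvalue(x, y, n_b = 500, seed = 11)
  r2 <- ks_bootstrap_pvalue(x, y, n_b = 500, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 501)  # add-one floor: never exactly zero
  # well-separated Poisson rates: strong rejection across repetitions
  ps <- vapply(1:20, function(r) {
    xs <- withr::with_seed(700 + r, rpois(100, 3))
    ys <- withr::with_seed(800 + r, rpois(100, 8))
    ks_bootstrap_pvalue(xs, ys, n_b = 500, seed = r)$p_value
  }, numeric(1))
  expect_true(all(ps < 0.01))
})

test_that("the density-equality permutation test detects shifts and degeneracy", {
  x <- c(2, 3, 3, 4, 5)
  res <- permutation_density_test(x, x, n_perm = 99, seed = 5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  a <- withr::with_seed(64, rpois(100, 3))
  b <- withr::with_seed(65, rpois(100, 3) + 8)  # strong shift
  res <- permutation_density_test(a, b, n_perm = 300, seed = 6)
  expect_lte(res$p_value, 0.01)

  expect_warning(res <- permutation_density_test(rep(2, 10), rep(2, 10),
                                                 n_perm = 50, seed = 1),
                 "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("distance covariance vanishes for constants and finds dependence", {
  x <- withr::with_seed(66, rnorm(50))
  expect_equal(distance_covariance(rep(2, 50), x), 0)
  expect_equal(distance_covariance(x, rep(-1, 50)), 0)
  # invariance under adding a constant to either argument
  y <- withr::with_seed(67, rnorm(50))
  expect_equal(distance_covariance(x, y), distance_covariance(x + 5, y - 3))
  expect_error(distance_covariance(1:4, 1:5), "lengths differ")

  dep <- dcov_bootstrap_test(x, x, n_b = 300, seed = 8)
  expect_gt(dep$statistic, 0)
  expect_lte(dep$p_value, 0.01)
  # determinism of the seeded bootstrap
  expect_identical(dep$p_value, dcov_bootstrap_test(x, x, n_b = 300, seed = 8)$p_value)
})

test_that("Pearson matrices recover programmed channel correlations", {
  dup <- withr::with_seed(68, {
    v <- rnorm(100, 500, 80)
    cbind(a = v, b = v, c = rnorm(100, 500, 80))
  })
  pm <- pearson_matrix(dup)
  expect_equal(pm$r["a", "b"], 1)
  expect_true(all(diag(pm$r) == 1))

  indep <- withr::with_seed(69, matrix(rlnorm(2000, 5, 0.35), ncol = 4))
  pm <- pearson_matrix(indep)
  off <- pm$r[upper.tri(pm$r)]
  expect_lte(max(abs(off)), 0.15)

  rho <- 0.8
  corr <- withr::with_seed(70, {
    z1 <- rnorm(500); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(500)
    cbind(z1, z2, rnorm(500), rnorm(500))
  })
  pm <- pearson_matrix(corr)
  expect_lt(abs(pm$r[1, 2] - rho), 0.1)

  flat <- cbind(rep(1, 10), rnorm(10), rnorm(10))
  pm <- pearson_matrix(flat)
  expect_true(is.na(pm$r[1, 2]))
})

test_that("the chi-squared homogeneity test matches hand computation", {
  a <- c(30, 25, 45)
  res <- chisq_population_test(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- chisq_population_test(c(10, 20), c(20, 10))
  expect_equal(res$statistic, 20 / 3)
  # symmetry under swapping the samples
  swapped <- chisq_population_test(c(20, 10), c(10, 20))
  expect_equal(res$statistic, swapped$statistic)
  expect_equal(res$p_value, swapped$p_value)

  # everything pooled into one class -> untestable
  expect_error(chisq_population_test(c(1, 1, 1), c(1, 1, 1)), "fewer than 2")
})

test_that("median fold change reports ratios and degenerate references", {
  expect_equal(median_fold(c(3, 3, 3), c(1, 1, 1))$ratio, 3)
  expect_equal(median_fold(4:10, 4:10)$ratio, 1)
  expect_warning(mf <- median_fold(c(2, 3), c(0, 0)), "not finite")
  expect_true(mf$degenerate)
  expect_identical(mf$ratio, Inf)
})

test_that("resampling p-values respect the add-one floor", {
  x <- withr::with_seed(71, rpois(30, 2))
  y <- x + 50  # maximally separated
  for (res in list(ks_bootstrap_pvalue(x, y, n_b = 99, seed = 1),
                   permutation_density_test(x, y, n_perm = 99, seed = 1),
                   dcov_bootstrap_test(as.numeric(1:30), as.numeric(1:30),
                                       n_b = 99, seed = 1))) {
    expect_gte(res$p_value, 1 / 100)
    expect_lte(res$p_value, 1)
  }
})
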