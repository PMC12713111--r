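test_that("point-null full-Cauchy BF matches an independent quadrature", {
  skip_if_not_installed("pracma")
  pr <- rsa_prior()
  for (tstat in seq(0, 6, by = 0.5)) {
    for (n in c(5, 10, 20, 50)) {
      got <- as.numeric(objspace:::bf_from_t(tstat, n, pr))
      want <- oracle_jzs_bf(tstat, n)
      expect_lt(abs(got - want) / want, 1e-4)
    }
  }
})

test_that("interval-excluded prior behaves sensibly at the extremes", {
  set.seed(1)
  vals <- 0.5 + rnorm(20, 0, 0.03)
  vals <- vals - mean(vals) + 0.5        # force t = 0
  expect_lt(as.numeric(bf_one_sample(vals, 0.5)), 1)
  big <- vals + 0.4                       # shift >> sd
  expect_gt(as.numeric(bf_one_sample(big, 0.5)), 100)
  expect_error(bf_one_sample(rep(0.5, 10), 0.5), "zero variance")
  expect_error(bf_one_sample(0.7, 0.5), "at least 2")
  # interval-null variant: the null averages the likelihood over the
  # excluded band, penalizing a strong effect less than the point null
  pr_int <- prior_spec(null_type = "interval")
  b_int <- as.numeric(bf_one_sample(big, 0.5, pr_int))
  b_pt <- as.numeric(bf_one_sample(big, 0.5))
  expect_true(is.finite(b_int) && b_int > 0)
  expect_lt(b_int, b_pt)
  expect_error(prior_spec(exclude = NULL, null_type = "interval"),
               "requires an exclusion interval")
})

test_that("BF is invariant to rescaling values and null together", {
  set.seed(2)
  v <- rnorm(15, 0.6, 0.1)
  b1 <- as.numeric(bf_one_sample(v, 0.5))
  b2 <- as.numeric(bf_one_sample(10 * v, 5))
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("truncating the alternative lowers the BF under the null", {
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(12, 0, 1)
    b_trunc <- as.numeric(bf_one_sample(v, 0, prior_spec()))
    b_full <- as.numeric(bf_one_sample(v, 0, rsa_prior()))
    expect_lte(b_trunc, b_full * (1 + 1e-10))
  }
})

test_that("evidence for the null accumulates with sample size", {
  set.seed(4)
  med_bf <- vapply(c(10, 40, 160), function(n) {
    median(replicate(40, as.numeric(bf_one_sample(rnorm(n), 0))))
  }, numeric(1))
  expect_true(all(diff(med_bf) < 0))
})

test_that("BF timecourses are calibrated on null data and detect real effects", {
  set.seed(5)
  frac_pos <- replicate(50, {
    m <- matrix(rnorm(20 * 10, 0.5, 0.02), 20)
    b <- bf_timecourse(m, 0.5)
    c(mean(b$bf > 1), median(b$bf))
  })
  expect_lt(mean(frac_pos[1, ]), 0.2)   # few false positives
  expect_lt(median(frac_pos[2, ]), 1)   # median BF favors the null
  # a strong injected effect at timepoints 4:6
  m <- matrix(rnorm(20 * 10, 0.5, 0.02), 20)
  m[, 4:6] <- m[, 4:6] + 0.1
  b <- bf_timecourse(m, 0.5, times_ms = seq(0, 90, by = 10))
  expect_true(all(b$bf[4:6] > 10))
  # degenerate single-timepoint input
  b1 <- bf_timecourse(matrix(rnorm(20, 0.6, 0.05), 20, 1), 0.5)
  expect_length(b1$bf, 1L)
})

test_that("paired difference BFs honor pairing and the zero-difference limit", {
  set.seed(6)
  a <- matrix(rnorm(15 * 5, 0.55, 0.03), 15)
  expect_error(bf_difference(a, a[1:10, ]), "identical")
  b0 <- bf_difference(a, a)
  expect_true(all(b0$bf < 1))            # a = b exactly
  shift <- a + matrix(rnorm(15 * 5, 0.08, 0.01), 15)
  bs <- bf_difference(shift, a)
  expect_true(all(bs$bf > 3))
})

test_that("beta BFs use the full two-sided prior and propagate errors", {
  set.seed(7)
  null_betas <- matrix(rnorm(20 * 8, 0, 0.05), 20)
  b <- bf_beta(null_betas)
  expect_lt(median(b$bf), 1)
  strong <- matrix(rnorm(20 * 3, 0.5, 0.05), 20)
  expect_true(all(bf_beta(strong)$bf > 100))
  expect_error(bf_beta(matrix(0, 10, 4)), "zero variance")
})
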