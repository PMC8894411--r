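test_that("ICC(A,1) matches hand-computed ANOVA values on small tables", {
  # identical raters with spread: perfect agreement, degenerate CI
  d <- data.frame(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2))
  fit <- icc_absolute_agreement(d, a, b)
  expect_equal(fit$icc, 1)
  expect_equal(c(fit$icc_ci_low, fit$icc_ci_high), c(1, 1))

  # constant-offset pair: hand ANOVA gives MSR = 2, MSC = 1.5, MSE = 0 -> 2/3
  d <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))
  fit <- icc_absolute_agreement(d, a, b, model = "mixed")
  expect_equal(fit$icc, 2 / 3, tolerance = 1e-12)
  m <- as.matrix(d)
  expect_equal(fit$icc, oracle_icc_a1(m), tolerance = 1e-10)
  expect_equal(fit$icc, oracle_icc_sums(m), tolerance = 1e-12)
  expect_true(fit$icc_ci_low <= fit$icc && fit$icc <= fit$icc_ci_high)
})

test_that("ICC agrees with the aov and sums-of-squares oracles on random tables", {
  for (s in 1:40) {
    withr::with_seed(200 + s, {
      n <- sample(4:12, 1)
      k <- sample(2:4, 1)
      m <- matrix(rnorm(n * k, mean = 10, sd = 3), n, k) +
        rnorm(n, sd = 4)  # subject effects
    })
    fit <- icc_absolute_agreement(as.data.frame(m))
    expect_equal(fit$icc, oracle_icc_a1(m), tolerance = 1e-9)
    expect_equal(fit$icc, oracle_icc_sums(m), tolerance = 1e-9)
  }
})

test_that("ICC of independent measurements is near zero at large n", {
  withr::with_seed(71, d <- data.frame(a = rnorm(10000), b = rnorm(10000)))
  fit <- icc_absolute_agreement(d, a, b)
  expect_lt(abs(fit$icc), 0.03)
})

test_that("absolute-agreement ICC penalizes offsets but not common affine maps", {
  withr::with_seed(72, {
    subj <- rnorm(50, sd = 5)
    d <- data.frame(a = subj + rnorm(50), b = subj + rnorm(50))
  })
  base <- icc_absolute_agreement(d, a, b)$icc
  shifted <- icc_absolute_agreement(dplyr::mutate(d, b = b + 3), a, b)$icc
  expect_lt(shifted, base)
  common <- icc_absolute_agreement(dplyr::mutate(d, a = 2 * a + 7, b = 2 * b + 7), a, b)$icc
  expect_equal(common, base, tolerance = 1e-10)
})

test_that("ICC input validation matches its preconditions", {
  expect_error(icc_absolute_agreement(data.frame(a = 1:2, b = 2:3)),
               class = "femver_error_samplesize")
  expect_error(icc_absolute_agreement(data.frame(a = 1:5)),
               class = "femver_error_samplesize")
  expect_error(icc_absolute_agreement(data.frame(a = rep(1, 5), b = rep(1, 5))),
               class = "femver_error_undefined")
  expect_error(icc_absolute_agreement(data.frame(a = c(1, NA, 3), b = c(1, 2, 3))),
               class = "femver_error_domain")
})

test_that("Bland-Altman bias and limits match the 1.96-SD definition", {
  d <- data.frame(a = c(1, 5, 9), b = c(1, 5, 9))
  ba <- suppressMessages(bland_altman(d, a, b))
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))

  # differences {1, 2, 3}: bias 2, SD 1, limits 2 -/+ 1.96
  d <- data.frame(a = c(2, 4, 6), b = c(1, 2, 3))
  ba <- bland_altman(d, a, b)
  expect_equal(ba$bias, 2)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0.04, 3.96))

  # swap antisymmetry: bias flips, width is invariant
  ba_swap <- bland_altman(d, b, a)
  expect_equal(ba_swap$bias, -ba$bias)
  expect_equal(ba_swap$loa_high - ba_swap$loa_low, ba$loa_high - ba$loa_low)
})

test_that("about 95% of normal differences fall inside the limits of agreement", {
  withr::with_seed(73, d <- data.frame(a = rnorm(100000, sd = 2), b = 0))
  ba <- bland_altman(d, a, b)
  inside <- mean(d$a >= ba$loa_low & d$a <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.005 / 0.95)
})

test_that("median absolute difference uses interpolated percentiles", {
  d <- data.frame(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(unlist(median_abs_diff(d, a, b)[1, 1:3], use.names = FALSE), c(0, 0, 0))

  # |a - b| = {1, 2, 3, 4}: median 2.5, quartiles 1.75 and 3.25
  d <- data.frame(a = c(1, 2, 3, 4), b = 0)
  mad <- median_abs_diff(d, a, b)
  expect_equal(mad$median_abs_diff, 2.5)
  expect_equal(c(mad$mad_iqr_low, mad$mad_iqr_high), c(1.75, 3.25))

  # half-normal: median |X| = 0.6745 sigma
  withr::with_seed(74, d <- data.frame(a = rnorm(200000, sd = 1.93), b = 0))
  expect_equal(median_abs_diff(d, a, b)$median_abs_diff, 1.30, tolerance = 0.02)
})

test_that("agreement_report composes the three statistics consistently", {
  withr::with_seed(75, {
    subj <- rnorm(40, 10, 5)
    d <- data.frame(x = subj + rnorm(40), y = subj + rnorm(40))
  })
  rep <- agreement_report(d, x, y)
  expect_equal(rep$icc, icc_absolute_agreement(d, x, y)$icc)
  ba <- bland_altman(d, x, y)
  expect_equal(c(rep$bias, rep$loa_low, rep$loa_high), c(ba$bias, ba$loa_low, ba$loa_high))
  expect_true(rep$icc_ci_low <= rep$icc && rep$icc <= rep$icc_ci_high)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_true(rep$mad_iqr_low <= rep$median_abs_diff &&
                rep$median_abs_diff <= rep$mad_iqr_high)
})

test_that("tidy, glance and autoplot methods return the expected shapes", {
  d <- data.frame(a = c(1, 2, 3, 5), b = c(2, 3, 4, 7))
  fit <- icc_absolute_agreement(d, a, b)
  expect_named(tidy(fit), c("term", "estimate", "conf.low", "conf.high", "model"))
  expect_equal(glance(fit)$n, 4)
  ba <- bland_altman(d, a, b)
  expect_named(tidy(ba), c("bias", "loa_low", "loa_high", "sd_diff", "n"))
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})
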