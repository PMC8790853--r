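test_that("affiliation weights are validated", {
  expect_silent(affiliation_weights(c(0.2, 0.5, 0.3)))
  expect_error(affiliation_weights(c(0.5, 0.5)), "3")
  expect_error(affiliation_weights(c(0.6, 0.5, -0.1)), "nonnegative")
  expect_error(affiliation_weights(c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("arm-level expected loss reproduces the reporting formulas", {
  # single draw: a000 = 6, beta4 = -3, beta9 = -0.9, beta10 = -0.6
  mat <- random_model1_draws(1)
  mat[1, ] <- 0
  mat[1, c("a000", "beta4", "beta9", "beta10")] <- c(6, -3, -0.9, -0.6)
  mat[1, c("sigma", "sigma_gamma", "sigma_eta")] <- 1
  s <- make_samples(mat)
  d <- arm_expected_loss(s)
  expect_equal(unname(d[1, "Delta1"]), 2.5)
  # reference-affiliation-only weights isolate a000 + beta4
  d_ref <- arm_expected_loss(s, affiliation_weights(c(1, 0, 0)))
  expect_equal(unname(d_ref[1, "Delta1"]), 3)
  # arm formulas at month 24
  mat2 <- random_model1_draws(200, seed = 8L)
  s2 <- make_samples(mat2)
  d2 <- arm_expected_loss(s2)
  base <- mat2[, "a000"] + mat2[, "beta4"] +
    (mat2[, "beta9"] + mat2[, "beta10"]) / 3
  expect_equal(unname(d2[, "Delta1"]), unname(base), tolerance = 1e-12)
  expect_equal(unname(d2[, "Delta2"]),
               unname(base + mat2[, "beta1"] + mat2[, "beta7"]),
               tolerance = 1e-12)
  expect_equal(unname(d2[, "Delta3"]),
               unname(base + mat2[, "beta2"] + mat2[, "beta8"]),
               tolerance = 1e-12)
  # months 6 and 18 use their own time and interaction terms
  d6 <- arm_expected_loss(s2, month = 6)
  expect_equal(unname(d6[, "Delta2"] - d6[, "Delta1"]),
               unname(mat2[, "beta1"]), tolerance = 1e-12)
  d18 <- arm_expected_loss(s2, month = 18)
  expect_equal(unname(d18[, "Delta3"] - d18[, "Delta1"]),
               unname(mat2[, "beta2"] + mat2[, "beta6"]), tolerance = 1e-12)
})

test_that("posterior mean of a linear quantity equals the linear combination of means", {
  mat <- random_model1_draws(5000, seed = 3L)
  s <- make_samples(mat)
  d <- arm_expected_loss(s)
  pm <- colMeans(mat)
  expect_equal(mean(d[, "Delta1"]),
               pm[["a000"]] + pm[["beta4"]] +
                 (pm[["beta9"]] + pm[["beta10"]]) / 3,
               tolerance = 1e-10)
})

test_that("exceedance probabilities count strictly positive draws", {
  expect_equal(exceedance_probability(c(-1, -1, rep(1, 8))), 0.8)
  expect_equal(exceedance_probability(rep(0, 10)), 0)
  set.seed(5)
  for (i in 1:100) {
    x <- rnorm(50)
    expect_identical(exceedance_probability(x), sum(x > 0) / 50)
  }
})

test_that("threshold probabilities follow the predictive normal integral", {
  mat <- random_model1_draws(1)
  mat[1, ] <- 0
  # posterior-mean plug-in from the three-level analysis of the study
  mat[1, c("a000", "beta4")] <- c(5.5, -3)  # Delta1 = 2.5 with zero beta9/10
  mat[1, c("sigma", "sigma_gamma", "sigma_eta")] <- c(3.92, 6.66, 0.98)
  s <- make_samples(mat)
  sd_pred <- sqrt(3.92^2 + 6.66^2 + 0.98^2)
  expect_equal(threshold_probability(s, threshold = 5, arm = 1)[1],
               1 - pnorm((5 - 2.5) / sd_pred), tolerance = 1e-12)
  # threshold at the arm mean gives exactly one half
  expect_equal(threshold_probability(s, threshold = 2.5, arm = 1)[1], 0.5)
  # strictly decreasing in the threshold, hence p5 >= p10 draw by draw
  mat2 <- random_model1_draws(500, seed = 4L)
  s2 <- make_samples(mat2)
  p5 <- threshold_probability(s2, threshold = 5, arm = 2)
  p7 <- threshold_probability(s2, threshold = 7, arm = 2)
  p10 <- threshold_probability(s2, threshold = 10, arm = 2)
  expect_true(all(p5 > p7 & p7 > p10))
})

test_that("per-draw signs of contrasts and threshold-probability differences agree", {
  mat <- random_model1_draws(2000, seed = 6L)
  dq <- derive_quantities(make_samples(mat))
  dr <- dq$draws
  expect_true(all(sign(dr[, "delta2"]) == sign(dr[, "dp5_2"])))
  expect_true(all(sign(dr[, "delta2"]) == sign(dr[, "dp10_2"])))
  expect_true(all(sign(dr[, "delta3"]) == sign(dr[, "dp5_3"])))
  expect_true(all(dr[, "p5_arm1"] >= dr[, "p10_arm1"]))
  # identical exceedance probabilities for the continuous and dichotomized
  # contrasts, as an identity
  cn <- arm_contrasts(dq)
  expect_identical(cn$prob_gt0_2, exceedance_probability(dr[, "dp5_2"]))
  expect_identical(cn$prob_gt0_3, exceedance_probability(dr[, "dp10_3"]))
})

test_that("arm contrasts are invariant to the affiliation weights", {
  mat <- random_model1_draws(1000, seed = 9L)
  s <- make_samples(mat)
  d_eq <- derive_quantities(s, affiliation_weights())
  d_pp <- derive_quantities(s, affiliation_weights(c(0.62, 0.2, 0.18)))
  expect_identical(d_eq$draws[, "delta2"], d_pp$draws[, "delta2"])
  expect_identical(d_eq$draws[, "delta3"], d_pp$draws[, "delta3"])
  # the arm means themselves do move with the weights
  expect_false(identical(d_eq$draws[, "Delta1"], d_pp$draws[, "Delta1"]))
})

test_that("credible intervals use the linear-interpolation quantile convention", {
  ci <- credible_interval(rep(4.2, 10))
  expect_equal(c(ci$lower, ci$mean, ci$upper), c(4.2, 4.2, 4.2))
  ci <- credible_interval(1:100, level = 0.95)
  expect_equal(c(ci$lower, ci$upper), c(3.475, 97.525), tolerance = 1e-12)
  expect_equal(ci$mean, 50.5)
  # nestedness: widening the level never shrinks the interval
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(200)
    lo <- credible_interval(x, 0.5)
    hi <- credible_interval(x, 0.95)
    expect_lte(hi$lower, lo$lower)
    expect_gte(hi$upper, lo$upper)
  }
  expect_error(credible_interval(numeric(0)), "2 draws")
  expect_error(credible_interval(1:10, level = 1.2), "level")
})

test_that("kernel density curves are normalized, symmetric and consistent", {
  set.seed(2)
  x <- rnorm(2000)
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x) - 8 * bw, max(x) + 8 * bw, length.out = 2001)
  kd <- kde_curve(x, grid)
  expect_true(all(kd$density >= 0))
  integral <- sum((kd$density[-1] + kd$density[-2001]) / 2 * diff(kd$grid))
  expect_lt(abs(integral - 1), 1e-3)
  # symmetric draws on a symmetric grid give a symmetric curve
  xs <- c(x, -x)
  gs <- seq(-4, 4, length.out = 801)
  kds <- kde_curve(xs, gs)
  expect_equal(kds$density, rev(kds$density), tolerance = 1e-12)
  # consistency against the analytic standard normal density; the bound
  # allows for the rule-of-thumb smoothing bias (~0.003 at the mode for
  # this sample size) plus pointwise Monte-Carlo noise (sd ~0.004) taken
  # over the whole grid
  set.seed(3)
  big <- rnorm(50000)
  gb <- seq(-4, 4, length.out = 401)
  kb <- kde_curve(big, gb)
  expect_lt(max(abs(kb$density - dnorm(gb))), 0.015)
  expect_error(kde_curve(rep(1, 5), gb), "distinct")
})
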