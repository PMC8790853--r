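# Hand-built five-observation fixture with non-trivial values at every level.
fixture_state_design <- function(variant = "model2") {
  tab <- data.frame(
    site_id = c(1L, 1L, 2L, 2L, 2L),
    affiliation = c("A1", "A1", "A2", "A2", "A2"),
    arm = c("individual", "individual", "phone_group", "phone_group",
            "phone_group"),
    group_id = c(0L, 0L, 1L, 1L, 1L),
    patient_id = c(1L, 1L, 2L, 2L, 3L),
    visit_month = c(6L, 24L, 6L, 18L, 24L),
    pct_weight_loss = c(4.2, 1.1, 8.3, 5.5, 3.7))
  design <- build_design(tab, variant)
  state <- parameter_state(
    a000 = 6, beta = c(1.5, 2, -2.2, -3, 0.4, -1.8, -0.3, -0.1, -0.9, -0.4),
    eta = c(0.5, -0.7), gamma = c(1.1, -2.3, 0.6),
    sigma = 2.5, sigma_gamma = 6, sigma_eta = 1,
    theta = if (variant == "model2") 0.8,
    sigma_theta = if (variant == "model2") 1.3)
  list(design = design, state = state, table = tab)
}

test_that("pointwise log-likelihood matches an independent density oracle", {
  f <- fixture_state_design()
  st <- f$state
  d <- f$design
  ll <- loglik_pointwise(st, d)
  expect_length(ll, 5L)
  # oracle: assemble each mean by hand from the model equation and apply
  # the normal log-density formula directly
  beta <- st$beta
  mu_manual <- numeric(5)
  mu_manual[1] <- st$a000 + st$eta[1] + st$gamma[1]
  mu_manual[2] <- st$a000 + beta[4] + st$eta[1] + st$gamma[1]
  mu_manual[3] <- st$a000 + beta[2] + beta[9] + st$eta[2] + st$theta[1] +
    st$gamma[2]
  mu_manual[4] <- st$a000 + beta[2] + beta[3] + beta[6] + beta[9] +
    st$eta[2] + st$theta[1] + st$gamma[2]
  mu_manual[5] <- st$a000 + beta[2] + beta[4] + beta[8] + beta[9] +
    st$eta[2] + st$theta[1] + st$gamma[3]
  y <- f$table$pct_weight_loss
  oracle <- -0.5 * log(2 * pi) - log(st$sigma) -
    (y - mu_manual)^2 / (2 * st$sigma^2)
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("log-density scale properties hold at the mode", {
  tab <- data.frame(site_id = 1L, affiliation = "A1", arm = "individual",
                    group_id = 0L, patient_id = 1L, visit_month = 6L,
                    pct_weight_loss = 3)
  d <- build_design(tab, "model1")
  st <- parameter_state(a000 = 3, beta = rep(0, 10), eta = 0, gamma = 0,
                        sigma = 1, sigma_gamma = 1, sigma_eta = 1)
  expect_equal(loglik_pointwise(st, d)[1], -0.5 * log(2 * pi),
               tolerance = 1e-12)
  st2 <- st
  st2$sigma <- 2
  expect_equal(loglik_pointwise(st, d)[1] - loglik_pointwise(st2, d)[1],
               log(2), tolerance = 1e-12)
  st_bad <- st
  st_bad$sigma <- -1
  expect_error(loglik_pointwise(st_bad, d), "sigma")
})

test_that("the prior is flat in the fixed effects and half-normal in the SDs", {
  st <- parameter_state(a000 = 0, beta = rep(0, 10), eta = numeric(0),
                        gamma = numeric(0), sigma = 3, sigma_gamma = 2,
                        sigma_eta = 1)
  st_shift <- st
  st_shift$beta <- st$beta + 100
  st_shift$a000 <- -50
  expect_equal(logprior(st, variant = "model1"),
               logprior(st_shift, variant = "model1"))
  # half-normal scale-10 term: sigma = 10 vs sigma -> 0+ differ by -0.5
  st10 <- st
  st10$sigma <- 10
  st0 <- st
  st0$sigma <- 1e-9
  expect_equal(logprior(st10, variant = "model1") -
                 logprior(st0, variant = "model1"), -0.5, tolerance = 1e-6)
  # out of support
  st_neg <- st
  st_neg$sigma_gamma <- -1
  expect_identical(logprior(st_neg, variant = "model1"), -Inf)
})

test_that("the log posterior is the sum of likelihood and prior", {
  f <- fixture_state_design()
  lp <- logposterior(f$state, f$design)
  expect_equal(lp, sum(loglik_pointwise(f$state, f$design)) +
                 logprior(f$state, variant = "model2"), tolerance = 1e-10)
  bad <- f$state
  bad$sigma_eta <- -2
  expect_identical(logposterior(bad, f$design), -Inf)
})

test_that("likelihood is location-equivariant in the intercept", {
  f <- fixture_state_design("model1")
  st <- f$state
  st$theta <- NULL
  st$sigma_theta <- NULL
  st$eta <- c(0, 0)
  st$gamma <- rep(0, 3)
  d <- f$design
  d2 <- d
  d2$y <- d$y + 7
  st2 <- st
  st2$a000 <- st$a000 + 7
  expect_equal(loglik_pointwise(st, d), loglik_pointwise(st2, d2),
               tolerance = 1e-12)
})

test_that("the four-level likelihood nests the three-level model", {
  f2 <- fixture_state_design("model2")
  f1 <- fixture_state_design("model1")
  st2 <- f2$state
  st2$theta <- 0   # group effect switched off
  expect_equal(loglik_pointwise(st2, f2$design),
               loglik_pointwise(f1$state, f1$design), tolerance = 1e-12)
  # the log-posterior difference is exactly the group-level prior terms
  lp2 <- logposterior(st2, f2$design)
  lp1 <- logposterior(f1$state, f1$design)
  extra <- -st2$sigma_theta^2 / 200 +
    sum(stats::dnorm(0, 0, st2$sigma_theta, log = TRUE))
  expect_equal(lp2 - lp1, extra, tolerance = 1e-10)
})
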