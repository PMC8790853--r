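test_that("noise-free degenerate configuration yields a constant outcome", {
  fx <- table1_fixed()
  fx[] <- 0
  fx["a000"] <- 5
  cfg <- generator_config(n_sites = 6L, patients_per_site = 3L,
                          group_size = 2L, true_fixed = fx,
                          true_sds = c(sigma = 0, sigma_gamma = 0,
                                       sigma_eta = 0, sigma_theta = 0),
                          seed = 1L)
  tr <- generate_trial(cfg)
  expect_true(all(tr$table$pct_weight_loss == 5))
  expect_equal(tr$truth$eta, rep(0, 6))
})

test_that("default configuration reproduces the trial's design structure", {
  tr <- generate_trial(generator_config(seed = 2L))
  tab <- tr$table
  site_arm <- unique(tab[c("site_id", "arm")])
  expect_equal(nrow(site_arm), 36L)
  expect_equal(as.integer(table(site_arm$arm)), rep(12L, 3))
  # each arm holds an equal number of sites from every affiliation
  site_aff <- unique(tab[c("site_id", "arm", "affiliation")])
  expect_true(all(table(site_aff$arm, site_aff$affiliation) == 4L))
  # every patient appears at exactly the three visits
  expect_true(all(table(tab$patient_id) == 3L))
  expect_equal(length(unique(tab$patient_id)), 36L * 39L)
  # group ids exactly on the group-based arms
  expect_true(all((tab$group_id == 0L) == (tab$arm == "individual")))
  # intervention-group effects are exactly zero for individual-arm patients
  ind_pat <- unique(tab$patient_id[tab$arm == "individual"])
  expect_true(all(tr$truth$group_of_patient[ind_pat] == 0L))
  # groups respect the target size (median 14 under the default config)
  gsz <- table(unique(tab[c("patient_id", "group_id")])$group_id)
  gsz <- gsz[names(gsz) != "0"]
  expect_equal(unname(stats::median(gsz)), 14)
})

test_that("identical configurations and seeds give identical tables", {
  cfg <- generator_config(n_sites = 6L, patients_per_site = 5L, seed = 99L,
                          dropout_rate = 0.2)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  t1 <- generate_trial(cfg)$table
  t2 <- generate_trial(generator_config(n_sites = 6L, patients_per_site = 5L,
                                        seed = 100L, dropout_rate = 0.2))$table
  expect_false(identical(t1, t2))
  # MCAR dropout removes roughly the configured fraction of rows
  expect_lt(nrow(t1), 6 * 5 * 3)
})

test_that("total outcome variance matches the summed variance components", {
  # moment-matching against an independent Monte-Carlo oracle: resimulate
  # with 10 different seeds and compare the empirical variance of y around
  # the fixed-effect mean with sigma^2 + sigma_gamma^2 + sigma_eta^2
  sds <- table1_sds(sigma_theta = 0)
  expected <- sum(sds[c("sigma", "sigma_gamma", "sigma_eta")]^2)
  expect_equal(round(expected, 2), 60.68)
  one_var <- function(seed) {
    tr <- generate_trial(generator_config(patients_per_site = 100L,
                                          true_sds = sds, seed = seed))
    tab <- tr$table
    fx <- tr$truth$true_fixed
    x1 <- as.numeric(tab$arm == "inclinic_group")
    x2 <- as.numeric(tab$arm == "phone_group")
    t18 <- as.numeric(tab$visit_month == 18)
    t24 <- as.numeric(tab$visit_month == 24)
    mu <- fx[["a000"]] + fx[["beta1"]] * x1 + fx[["beta2"]] * x2 +
      fx[["beta3"]] * t18 + fx[["beta4"]] * t24 +
      fx[["beta5"]] * x1 * t18 + fx[["beta6"]] * x2 * t18 +
      fx[["beta7"]] * x1 * t24 + fx[["beta8"]] * x2 * t24 +
      fx[["beta9"]] * (tab$affiliation == "A2") +
      fx[["beta10"]] * (tab$affiliation == "A3")
    mean((tab$pct_weight_loss - mu)^2)
  }
  vars <- vapply(1:10, one_var, numeric(1))
  expect_lt(abs(mean(vars) - expected) / expected, 0.05)
  expect_lt(abs(vars[1] - expected) / expected, 0.05)
})

test_that("level-averaged residuals recover each variance component", {
  # large-n decomposition: compare the variance of level means of the
  # residuals (other levels' realized effects subtracted via the truth
  # record) against the realized variance of that level's draws plus the
  # known averaging correction
  sds <- c(sigma = 3.92, sigma_gamma = 6.66, sigma_eta = 0.98,
           sigma_theta = 1.28)
  tr <- generate_trial(generator_config(n_sites = 201L,
                                        patients_per_site = 50L,
                                        group_size = 10L,
                                        true_sds = sds, seed = 77L))
  tab <- tr$table
  truth <- tr$truth
  fx <- truth$true_fixed
  x1 <- as.numeric(tab$arm == "inclinic_group")
  x2 <- as.numeric(tab$arm == "phone_group")
  t18 <- as.numeric(tab$visit_month == 18)
  t24 <- as.numeric(tab$visit_month == 24)
  mu <- fx[["a000"]] + fx[["beta1"]] * x1 + fx[["beta2"]] * x2 +
    fx[["beta3"]] * t18 + fx[["beta4"]] * t24 +
    fx[["beta5"]] * x1 * t18 + fx[["beta6"]] * x2 * t18 +
    fx[["beta7"]] * x1 * t24 + fx[["beta8"]] * x2 * t24 +
    fx[["beta9"]] * (tab$affiliation == "A2") +
    fx[["beta10"]] * (tab$affiliation == "A3")
  theta_obs <- ifelse(tab$group_id > 0, truth$theta[pmax(tab$group_id, 1)], 0)
  eps <- tab$pct_weight_loss - mu - truth$eta[tab$site_id] - theta_obs -
    truth$gamma[tab$patient_id]
  # residual level
  expect_lt(abs(stats::var(eps) - sds[["sigma"]]^2) / sds[["sigma"]]^2, 0.05)
  # patient level: visit-mean of (gamma + eps)
  pm <- tapply(truth$gamma[tab$patient_id] + eps, tab$patient_id, mean)
  nv <- 3
  exp_pat <- stats::var(truth$gamma) + sds[["sigma"]]^2 / nv
  expect_lt(abs(stats::var(pm) - exp_pat) / exp_pat, 0.05)
  # site level: site-mean of (eta + eps)
  sm <- tapply(truth$eta[tab$site_id] + eps, tab$site_id, mean)
  nobs_site <- 50 * nv
  exp_site <- stats::var(truth$eta) + sds[["sigma"]]^2 / nobs_site
  expect_lt(abs(stats::var(sm) - exp_site) / exp_site, 0.05)
  # group level: group-mean of (theta + eps)
  grp <- tab$group_id > 0
  gm <- tapply(truth$theta[tab$group_id[grp]] + eps[grp], tab$group_id[grp],
               mean)
  nobs_grp <- 10 * nv
  exp_grp <- stats::var(truth$theta) + sds[["sigma"]]^2 / nobs_grp
  expect_lt(abs(stats::var(gm) - exp_grp) / exp_grp, 0.05)
})

test_that("invalid generator configurations are rejected naming the field", {
  expect_error(generator_config(n_sites = 10L), "n_sites")
  expect_error(generator_config(true_sds = c(sigma = -1, sigma_gamma = 1,
                                             sigma_eta = 1, sigma_theta = 1)),
               "true_sds")
  expect_error(generator_config(visit_months = integer(0)), "visit_months")
  expect_error(generator_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(generator_config(group_size = 0L), "group_size")
})
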