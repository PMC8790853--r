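# Shared fixtures: all data are generated in code at test time.

# Generating values used as synthetic truth throughout the suite: the
# posterior means of the three-level re-analysis of the motivating study.
table1_fixed <- function() generator_config()$true_fixed

table1_sds <- function(sigma_theta = 0) {
  sds <- generator_config()$true_sds
  sds["sigma_theta"] <- sigma_theta
  sds
}

# 6 sites (two per arm), one patient each, all three visits: 18 rows.
# The smallest balanced design whose 11-column fixed-effect matrix is
# full rank (fewer sites make the arm and affiliation columns collinear,
# which the flat prior cannot support).
tiny_trial <- function(seed = 42L) {
  generate_trial(generator_config(
    n_sites = 6L, patients_per_site = 1L, group_size = 1L,
    true_sds = table1_sds(sigma_theta = 1.28),
    seed = seed))
}

quick_sampler <- function(n_chains = 2L, n_warmup = 200L, n_keep = 300L,
                          seed = 1L, ...) {
  sampler_config(n_chains = n_chains, n_warmup = n_warmup, n_keep = n_keep,
                 seed = seed, ...)
}

# Build a posterior_draws object directly from a draws-by-parameters
# matrix of monitored values (single chain) — used to unit-test the
# derived-quantity operations without running the sampler.
make_samples <- function(mat, variant = "model1") {
  mat <- as.matrix(mat)
  arr <- array(NA_real_, dim = c(1L, nrow(mat), ncol(mat)),
               dimnames = list(NULL, NULL, colnames(mat)))
  arr[1L, , ] <- mat
  structure(list(draws = arr, parameters = colnames(mat),
                 monitored = colnames(mat), variant = variant,
                 n_sites = 0L, n_groups = 0L, n_patients = 0L,
                 seed = NA_integer_, n_chains = 1L, n_keep = nrow(mat)),
            class = "posterior_draws")
}

# random monitored-parameter draws on realistic posterior scales (percent
# weight loss units; predictive SD around 7-8 so that the 5%/10%
# thresholds stay within a few predictive SDs of the arm means), model1
# registry
random_model1_draws <- function(n, seed = 1L) {
  set.seed(seed)
  mat <- cbind(rnorm(n, 6, 1), matrix(rnorm(n * 10L), n, 10L),
               3.5 + abs(rnorm(n)), 6 + abs(rnorm(n)),
               0.5 + abs(rnorm(n, 0, 0.4)))
  colnames(mat) <- c("a000", paste0("beta", 1:10),
                     "sigma", "sigma_gamma", "sigma_eta")
  mat
}
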