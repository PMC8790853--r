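#' Prior specification
#'
#' Fixed effects (`a000`, `beta1`..`beta10`) carry an improper flat prior on
#' the real line; every standard deviation carries a half-normal prior with
#' the given scale (default 10, i.e. `N+(0, 10)`).
#'
#' @param sd_prior_scale positive half-normal scale for the SDs.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(sd_prior_scale = 10) {
  if (length(sd_prior_scale) != 1L || sd_prior_scale <= 0)
    stop("sd_prior_scale must be a single positive number")
  structure(list(sd_prior_scale = sd_prior_scale), class = "prior_spec")
}

#' A point in parameter space
#'
#' Bundles one value of every model parameter: intercept `a000`, the ten
#' fixed-effect coefficients, the per-site (`eta`), per-group (`theta`,
#' four-level model only) and per-patient (`gamma`) intercept deviations,
#' and the scale parameters `sigma` (residual), `sigma_gamma` (patient),
#' `sigma_eta` (site) and `sigma_theta` (group, four-level model only).
#'
#' @param a000 intercept (percent weight loss in the reference cell).
#' @param beta numeric vector of length 10 (`beta1`..`beta10`).
#' @param eta,gamma,theta random-intercept vectors; `theta = NULL` for the
#'   three-level model.
#' @param sigma,sigma_gamma,sigma_eta,sigma_theta standard deviations.
#' @return an object of class `parameter_state`.
#' @export
parameter_state <- function(a000, beta, eta, gamma,
                            sigma, sigma_gamma, sigma_eta,
                            theta = NULL, sigma_theta = NULL) {
  if (length(beta) != 10L) stop("beta must have length 10")
  structure(list(a000 = a000, beta = unname(beta),
                 eta = eta, theta = theta, gamma = gamma,
                 sigma = sigma, sigma_gamma = sigma_gamma,
                 sigma_eta = sigma_eta, sigma_theta = sigma_theta),
            class = "parameter_state")
}

state_mean <- function(state, design) {
  mu <- as.vector(design$X %*% c(state$a000, state$beta)) +
    state$eta[design$site] + state$gamma[design$patient]
  if (design$variant == "model2" && !is.null(state$theta)) {
    pos <- design$group > 0L
    mu[pos] <- mu[pos] + state$theta[design$group[pos]]
  }
  mu
}

#' Per-observation conditional log-likelihood
#'
#' Log density of each observation given all parameters and random effects:
#' `log N(y_n | mu_n, sigma^2)` with `mu_n` the fixed-effect linear
#' predictor plus the site, (group,) and patient intercepts of that row.
#'
#' @param state a [parameter_state()].
#' @param design a [build_design()] structure.
#' @return numeric vector, one log density per observation, in row order.
#' @export
loglik_pointwise <- function(state, design) {
  if (length(state$eta) != design$n_sites ||
      length(state$gamma) != design$n_patients)
    stop("random-effect vector lengths do not match the design")
  if (design$variant == "model2" && design$n_groups > 0L &&
      length(state$theta) != design$n_groups)
    stop("theta length does not match the number of groups")
  if (!is.finite(state$sigma) || state$sigma <= 0)
    stop("sigma must be strictly positive")
  stats::dnorm(design$y, state_mean(state, design), state$sigma, log = TRUE)
}

half_normal_lp <- function(s, scale) {
  if (!is.finite(s) || s <= 0) return(-Inf)
  -s^2 / (2 * scale^2)
}

#' Unnormalized log prior
#'
#' Flat fixed-effect terms contribute 0; each standard deviation `s`
#' contributes `-s^2 / (2 * scale^2)` inside its positive support and
#' `-Inf` outside; each random-effect vector contributes its
#' `N(0, sigma_level^2)` log density.
#'
#' @inheritParams loglik_pointwise
#' @param priors a [prior_spec()].
#' @param variant `"model1"` or `"model2"`.
#' @return a single (unnormalized) log density, possibly `-Inf`.
#' @export
logprior <- function(state, priors = prior_spec(),
                     variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  sc <- priors$sd_prior_scale
  lp <- half_normal_lp(state$sigma, sc) +
    half_normal_lp(state$sigma_gamma, sc) +
    half_normal_lp(state$sigma_eta, sc)
  if (variant == "model2")
    lp <- lp + half_normal_lp(state$sigma_theta, sc)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + sum(stats::dnorm(state$eta, 0, state$sigma_eta, log = TRUE)) +
    sum(stats::dnorm(state$gamma, 0, state$sigma_gamma, log = TRUE))
  if (variant == "model2" && length(state$theta))
    lp <- lp + sum(stats::dnorm(state$theta, 0, state$sigma_theta, log = TRUE))
  lp
}

#' Log posterior (up to a constant)
#'
#' Sum of [loglik_pointwise()] and [logprior()]; `-Inf` outside the prior
#' support.
#'
#' @inheritParams logprior
#' @param design a [build_design()] structure matching `variant`.
#' @return scalar log posterior.
#' @export
logposterior <- function(state, design, priors = prior_spec(),
                         variant = design$variant) {
  lp <- logprior(state, priors, variant)
  if (!is.finite(lp)) return(-Inf)
  lp + sum(loglik_pointwise(state, design))
}
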