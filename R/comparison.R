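# Model comparison: WAIC and Pareto-smoothed importance-sampling
# leave-one-out cross-validation on the conditional (observation-level)
# pointwise log-likelihood.

#' Pointwise log-likelihood matrix from posterior draws
#'
#' Evaluates the conditional per-observation log density at every retained
#' draw (random effects included), giving the draws-by-observations matrix
#' both information criteria operate on.
#'
#' @param samples a `posterior_draws` object (must retain the
#'   random-effect deviates, as [sample_posterior()] does).
#' @param design the `design_structure` the model was fitted to.
#' @return numeric matrix, rows = draws (chains stacked), columns =
#'   observations.
#' @export
loglik_matrix <- function(samples, design) {
  stopifnot(inherits(samples, "posterior_draws"),
            inherits(design, "design_structure"))
  fixef <- draw_matrix(samples, c("a000", paste0("beta", 1:10)))
  eta <- draw_matrix(samples, paste0("eta[", seq_len(samples$n_sites), "]"))
  gam <- draw_matrix(samples, paste0("gamma[", seq_len(samples$n_patients), "]"))
  sigma <- draw_matrix(samples, "sigma")[, 1L]
  MU <- tcrossprod(fixef, design$X) +
    eta[, design$site, drop = FALSE] +
    gam[, design$patient, drop = FALSE]
  if (samples$variant == "model2" && samples$n_groups > 0L) {
    the <- draw_matrix(samples, paste0("theta[", seq_len(samples$n_groups), "]"))
    pos <- which(design$group > 0L)
    MU[, pos] <- MU[, pos] + the[, design$group[pos], drop = FALSE]
  }
  RES2 <- sweep(MU, 2, design$y, "-")^2
  -0.5 * log(2 * pi) - log(sigma) - RES2 / (2 * sigma^2)
}

ic_se <- function(pointwise) sqrt(length(pointwise) * stats::var(pointwise))

new_ic_result <- function(method, pointwise, p_eff, pareto_k = NULL) {
  elpd <- sum(pointwise)
  structure(
    list(method = method,
         elpd = elpd,
         p_eff = p_eff,
         ic = -2 * elpd,
         se_elpd = ic_se(pointwise),
         se_ic = 2 * ic_se(pointwise),
         pointwise = pointwise,
         pareto_k = pareto_k,
         n_obs = length(pointwise)),
    class = "ic_result"
  )
}

#' @export
print.ic_result <- function(x, ...) {
  lab <- if (x$method == "waic") "WAIC" else "LOOIC"
  cat(sprintf("%s: %.1f (se %.1f), elpd %.1f, effective parameters %.1f, n = %d\n",
              lab, x$ic, x$se_ic, x$elpd, x$p_eff, x$n_obs))
  if (!is.null(x$pareto_k)) {
    k <- x$pareto_k[!is.na(x$pareto_k)]
    if (length(k))
      cat(sprintf("Pareto k: max %.2f, %d of %d above 0.7\n",
                  max(k), sum(k > 0.7), x$n_obs))
  }
  invisible(x)
}

#' Widely applicable information criterion
#'
#' Per observation `i`, `lppd_i = log mean_s exp(loglik_si)` (computed with
#' a max shift) and penalty `p_i = var_s loglik_si`;
#' `elpd_waic = sum(lppd_i - p_i)`, `waic = -2 elpd_waic`, and the standard
#' error is `sqrt(n * var_i(lppd_i - p_i))` on the elpd scale (doubled on
#' the deviance scale).
#'
#' @param loglik draws-by-observations log-likelihood matrix
#'   (see [loglik_matrix()]); at least 2 draws.
#' @return an object of class `ic_result`.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2L) stop("waic needs at least 2 draws")
  lppd <- apply(loglik, 2, log_mean_exp)
  p <- apply(loglik, 2, stats::var)
  new_ic_result("waic", pointwise = lppd - p, p_eff = sum(p))
}

# Generalized Pareto fit to exceedances z > 0 (location 0): profile
# likelihood maximized over a quantile-spaced grid in the rate-like
# parameter c = -shape/scale, whose admissible range (c < 1/max(z)) the
# grid respects by construction. Given c, the shape MLE is closed-form:
# xi(c) = mean(log(1 - c z)) maximizes the likelihood, with profile value
# n * (log(-c/xi) - xi - 1) continued through the exponential limit c -> 0.
# Returns shape xi and scale sigma = -xi/c.
gpd_fit <- function(z) {
  n <- length(z)
  z <- sort(z)
  m <- 30L + floor(sqrt(n))
  q1 <- z[max(1L, floor(n / 4 + 0.5))]
  cgrid <- 1 / z[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q1)
  prof <- vapply(cgrid, function(cj) {
    xi <- mean(log1p(-cj * z))
    if (!is.finite(xi) || xi == 0 || -cj / xi <= 0) return(-Inf)
    n * (log(-cj / xi) - xi - 1)
  }, numeric(1))
  chat <- cgrid[which.max(prof)]
  xi <- mean(log1p(-chat * z))
  list(shape = xi, scale = -xi / chat)
}

gpd_quantile <- function(p, shape, scale) {
  if (abs(shape) < 1e-12) return(-scale * log1p(-p))
  scale / shape * ((1 - p)^(-shape) - 1)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' For each observation the raw importance ratios are
#' `r_s = exp(-loglik_si)` (up to normalization). The largest
#' `M = ceiling(min(0.2 S, 3 sqrt(S)))` ratios are replaced by the expected
#' order statistics of a generalized Pareto distribution fitted to those
#' tail ratios (profile-likelihood point estimate of shape and scale over a
#' grid), weights are truncated at the raw maximum, and
#' `elpd_loo_i = log(sum_s w_s exp(loglik_si) / sum_s w_s)`;
#' `looic = -2 sum_i elpd_loo_i` with the same standard-error form as
#' [waic()]. The fitted Pareto shape is reported per observation; for an
#' observation with (numerically) constant ratios the plain importance
#' estimate is returned and the shape is flagged as `NA` (not estimated).
#'
#' @param loglik draws-by-observations log-likelihood matrix; at least 100
#'   draws (the tail fit needs a tail).
#' @return an object of class `ic_result` with a `pareto_k` vector.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 100L) stop("psis_loo needs at least 100 draws")
  M <- as.integer(ceiling(min(0.2 * S, 3 * sqrt(S))))
  n <- ncol(loglik)
  pointwise <- numeric(n)
  lppd <- numeric(n)
  ks <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_idx <- ord[(S - M + 1L):S]
    cutpoint <- lw[ord[S - M]]
    exceed <- exp(lw[tail_idx]) - exp(cutpoint)
    if (max(exceed) - min(exceed) > sqrt(.Machine$double.eps) * exp(cutpoint + 1)) {
      fit <- gpd_fit(exceed)
      ks[i] <- fit$shape
      qs <- gpd_quantile((seq_len(M) - 0.5) / M, fit$shape, fit$scale)
      smoothed <- log(exp(cutpoint) + qs)
      smoothed <- pmin(smoothed[rank(lw[tail_idx], ties.method = "first")], 0)
      lw[tail_idx] <- smoothed
    }
    pointwise[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
    lppd[i] <- log_mean_exp(ll)
  }
  new_ic_result("psis_loo", pointwise = pointwise,
                p_eff = sum(lppd - pointwise), pareto_k = ks)
}

#' Compare two fitted models on the deviance scale
#'
#' Difference row in the convention `model A - model B` (positive favors
#' B): criterion difference and the paired standard error
#' `2 * sqrt(n * var_i(elpd_i^A - elpd_i^B))`, which exploits the pointwise
#' pairing over the shared observations.
#'
#' @param res_a,res_b `ic_result`s computed with the same method on the
#'   identical observation set and order.
#' @return an object of class `model_comparison`.
#' @export
compare_models <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "ic_result"), inherits(res_b, "ic_result"))
  if (res_a$n_obs != res_b$n_obs)
    stop("models were evaluated on different numbers of observations")
  if (res_a$method != res_b$method)
    stop("cannot compare results from different criteria")
  d <- res_a$pointwise - res_b$pointwise
  structure(
    list(method = res_a$method,
         diff_ic = res_a$ic - res_b$ic,
         diff_elpd = sum(d),
         se_diff_elpd = ic_se(d),
         se_diff_ic = 2 * ic_se(d),
         n_obs = res_a$n_obs),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s difference (A - B): %.1f (se %.1f)\n",
              if (x$method == "waic") "WAIC" else "LOOIC",
              x$diff_ic, x$se_diff_ic))
  invisible(x)
}

#' Brute-force leave-one-out by refitting (test oracle)
#'
#' For each observation, refits the model on the remaining rows and
#' averages the held-out predictive density over the posterior draws. When
#' removing a row removes its patient (or site, or group) from the refitted
#' data entirely, the missing random effect is integrated out analytically:
#' its variance component is added to the predictive variance. Guarded to
#' small problems; intended as the exact oracle that [psis_loo()]
#' approximates.
#'
#' @param table observation table (at most 50 rows).
#' @param priors a [prior_spec()].
#' @param variant `"model1"` or `"model2"`.
#' @param config a [sampler_config()]; each refit derives its seed from
#'   `config$seed` and the held-out row.
#' @return list with `elpd` (summed log predictive density) and
#'   `pointwise`.
#' @export
exact_loo_refit <- function(table, priors = prior_spec(),
                            variant = c("model1", "model2"),
                            config = sampler_config()) {
  variant <- match.arg(variant)
  table <- validate_trial_table(table)
  n <- nrow(table)
  if (n > 50L) stop("exact_loo_refit is guarded to at most 50 observations")
  pointwise <- numeric(n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    design <- build_design(train, variant)
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- sample_posterior(design, priors, variant, cfg)
    row <- table[i, , drop = FALSE]
    x <- build_design(rbind(train[0, ], row), variant)$X[1L, ]
    fixef <- draw_matrix(fit, c("a000", paste0("beta", 1:10)))
    mu <- drop(fixef %*% x)
    sds <- draw_matrix(fit, c("sigma", "sigma_gamma", "sigma_eta"))
    v <- sds[, "sigma"]^2

    s_pos <- match(row$site_id, design$site_levels)
    if (is.na(s_pos)) v <- v + sds[, "sigma_eta"]^2
    else mu <- mu + draw_matrix(fit, paste0("eta[", s_pos, "]"))[, 1L]

    p_pos <- match(row$patient_id, design$patient_levels)
    if (is.na(p_pos)) v <- v + sds[, "sigma_gamma"]^2
    else mu <- mu + draw_matrix(fit, paste0("gamma[", p_pos, "]"))[, 1L]

    if (variant == "model2" && row$group_id > 0L) {
      g_pos <- match(row$group_id, design$group_levels)
      s_the <- draw_matrix(fit, "sigma_theta")[, 1L]
      if (is.na(g_pos)) v <- v + s_the^2
      else mu <- mu + draw_matrix(fit, paste0("theta[", g_pos, "]"))[, 1L]
    }
    pointwise[i] <- log_mean_exp(
      stats::dnorm(row$pct_weight_loss, mu, sqrt(v), log = TRUE))
  }
  list(elpd = sum(pointwise), pointwise = pointwise)
}

#' Write a two-model comparison as JSON
#'
#' Fields: `looic`, `looic_se`, `waic`, `waic_se`, `p_loo`, `p_waic` per
#' model, the difference row (`diff_looic`, `diff_looic_se`, `diff_waic`,
#' `diff_waic_se`, convention model A - model B), and the per-observation
#' Pareto shapes of model A and B.
#'
#' @param loo_a,loo_b,waic_a,waic_b `ic_result`s for the two models.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(loo_a, loo_b, waic_a, waic_b, path) {
  cmp_loo <- compare_models(loo_a, loo_b)
  cmp_waic <- compare_models(waic_a, waic_b)
  out <- list(
    model_a = list(looic = loo_a$ic, looic_se = loo_a$se_ic,
                   waic = waic_a$ic, waic_se = waic_a$se_ic,
                   p_loo = loo_a$p_eff, p_waic = waic_a$p_eff),
    model_b = list(looic = loo_b$ic, looic_se = loo_b$se_ic,
                   waic = waic_b$ic, waic_se = waic_b$se_ic,
                   p_loo = loo_b$p_eff, p_waic = waic_b$p_eff),
    diff_looic = cmp_loo$diff_ic, diff_looic_se = cmp_loo$se_diff_ic,
    diff_waic = cmp_waic$diff_ic, diff_waic_se = cmp_waic$se_diff_ic,
    pareto_k = list(model_a = loo_a$pareto_k, model_b = loo_b$pareto_k)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
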