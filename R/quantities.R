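# Derived posterior quantities: arm-level expected percent weight loss,
# arm contrasts, exceedance probabilities, posterior-predictive threshold
# probabilities, credible intervals and kernel density curves.

#' Affiliation averaging weights
#'
#' Nonnegative weights over the three affiliations (A1, A2, A3), summing to
#' 1. The default is the arithmetic average (1/3 each); weights
#' proportional to affiliation participant counts are an alternative that
#' leaves all arm contrasts unchanged (the affiliation coefficients cancel
#' in differences between arms).
#'
#' @param w numeric vector of 3 nonnegative weights summing to 1.
#' @return an object of class `affiliation_weights`.
#' @export
affiliation_weights <- function(w = c(1, 1, 1) / 3) {
  if (length(w) != 3L || any(w < 0))
    stop("weights must be 3 nonnegative numbers")
  if (abs(sum(w) - 1) > 1e-12)
    stop("weights must sum to 1 (within 1e-12)")
  structure(as.numeric(w), class = "affiliation_weights")
}

# named coefficient vector over (a000, beta1..beta10) picking out the
# expected percent weight loss of one arm at one month, affiliation-averaged
arm_mean_coefficients <- function(arm, month, weights) {
  co <- stats::setNames(numeric(11), c("a000", paste0("beta", 1:10)))
  co["a000"] <- 1
  co["beta9"] <- weights[2]
  co["beta10"] <- weights[3]
  if (month == 18) co["beta3"] <- 1
  if (month == 24) co["beta4"] <- 1
  if (arm == 2L) {
    co["beta1"] <- 1
    if (month == 18) co["beta5"] <- 1
    if (month == 24) co["beta7"] <- 1
  } else if (arm == 3L) {
    co["beta2"] <- 1
    if (month == 18) co["beta6"] <- 1
    if (month == 24) co["beta8"] <- 1
  }
  co
}

#' Per-draw arm-level expected percent weight loss
#'
#' For each posterior draw, the affiliation-averaged expected percent
#' weight loss of each arm at the requested visit month. At month 24 with
#' equal weights these are
#' `Delta1 = a000 + beta4 + (beta9 + beta10)/3`,
#' `Delta2 = Delta1 + beta1 + beta7`, and
#' `Delta3 = Delta1 + beta2 + beta8`.
#'
#' @param samples a `posterior_draws` object.
#' @param weights an [affiliation_weights()] vector.
#' @param month one of 6, 18, 24 (default 24, the primary endpoint).
#' @return matrix with one row per draw and columns `Delta1..Delta3`.
#' @export
arm_expected_loss <- function(samples, weights = affiliation_weights(),
                              month = 24) {
  if (!month %in% c(6, 18, 24)) stop("month must be one of 6, 18, 24")
  weights <- affiliation_weights(unclass(weights))
  dm <- draw_matrix(samples, c("a000", paste0("beta", 1:10)))
  out <- matrix(NA_real_, nrow(dm), 3L,
                dimnames = list(NULL, paste0("Delta", 1:3)))
  for (arm in 1:3)
    out[, arm] <- dm %*% arm_mean_coefficients(arm, month, weights)
  out
}

#' Exceedance probability of a contrast
#'
#' Fraction of posterior draws strictly greater than zero (ties at exactly
#' zero have probability zero under a continuous posterior and count as
#' non-exceeding).
#'
#' @param draws numeric vector of posterior draws of a contrast.
#' @return a probability in `[0, 1]`.
#' @export
exceedance_probability <- function(draws) {
  if (length(draws) == 0L) stop("exceedance_probability needs at least one draw")
  mean(draws > 0)
}

#' Per-draw posterior-predictive threshold probability
#'
#' Probability that a new participant in the given arm achieves at least
#' `threshold` percent weight loss at the given month. Per draw this is
#' `1 - Phi((threshold - Delta_arm) / sd_pred)` with
#' `sd_pred = sqrt(sigma^2 + sigma_gamma^2 + sigma_eta^2)`; under the
#' four-level model the group-level variance `sigma_theta^2` is added for
#' the two group-based arms (a new participant there is also assigned a new
#' intervention group) and omitted for the individual arm.
#'
#' @inheritParams arm_expected_loss
#' @param threshold clinical threshold in percent weight loss (e.g. 5, 10).
#' @param arm arm index 1 (individual), 2 (in-clinic group), 3 (phone group).
#' @return numeric vector of per-draw probabilities.
#' @export
threshold_probability <- function(samples, weights = affiliation_weights(),
                                  threshold, arm, month = 24) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (!arm %in% 1:3) stop("arm must be 1, 2 or 3")
  delta <- unname(arm_expected_loss(samples, weights, month)[, arm])
  sds <- draw_matrix(samples, c("sigma", "sigma_gamma", "sigma_eta"))
  v <- sds[, "sigma"]^2 + sds[, "sigma_gamma"]^2 + sds[, "sigma_eta"]^2
  if (samples$variant == "model2" && arm %in% c(2L, 3L))
    v <- v + draw_matrix(samples, "sigma_theta")[, 1L]^2
  if (any(v <= 0)) stop("nonpositive predictive variance draw")
  unname(1 - stats::pnorm((threshold - delta) / sqrt(v)))
}

#' Central credible interval and posterior mean
#'
#' The interval bounds are the linear-interpolation empirical quantiles
#' (the convention placing the k-th order statistic at probability
#' `(k-1)/(n-1)`, i.e. `quantile(..., type = 7)`), at
#' `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param draws numeric vector of posterior draws (at least 2).
#' @param level credible level in (0, 1), default 0.95.
#' @return an object of class `summary_interval`: list with `mean`,
#'   `lower`, `upper`, `level`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop("credible_interval needs at least 2 draws")
  if (length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  lo <- (1 - level) / 2
  q <- unname(stats::quantile(draws, c(lo, 1 - lo), type = 7, names = FALSE))
  structure(list(mean = mean(draws), lower = q[1L], upper = q[2L],
                 level = level),
            class = "summary_interval")
}

#' @export
print.summary_interval <- function(x, ...) {
  cat(sprintf("mean %.4g [%g%% CrI: %.4g, %.4g]\n",
              x$mean, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Gaussian kernel density curve
#'
#' Gaussian kernel density estimate evaluated on a caller-supplied grid,
#' with Silverman's rule-of-thumb bandwidth — the smoothed version of the
#' sampled histogram used for the posterior figures.
#'
#' @param draws numeric vector with at least 2 distinct values.
#' @param grid numeric vector of evaluation points.
#' @return data.frame with columns `grid` and `density`.
#' @export
kde_curve <- function(draws, grid) {
  if (length(unique(draws)) < 2L)
    stop("kde_curve needs at least 2 distinct draws (zero bandwidth otherwise)")
  bw <- stats::bw.nrd0(draws)
  dens <- vapply(grid,
                 function(g) mean(stats::dnorm(g - draws, sd = bw)),
                 numeric(1))
  data.frame(grid = grid, density = dens)
}

#' Derive the full set of posterior quantities of interest
#'
#' From one fitted model: per-draw arm-level expected percent weight loss
#' (`Delta1..3`), the contrasts versus the individual arm
#' (`delta2 = Delta2 - Delta1`, `delta3 = Delta3 - Delta1`), the
#' posterior-predictive probabilities of achieving each clinical threshold
#' per arm (`p5_arm1`, ... on the percent scale 0-1 per draw), and the
#' pairwise differences of those probabilities versus arm 1; plus posterior
#' summaries (mean, sd, credible interval, and exceedance probability for
#' the contrasts).
#'
#' @inheritParams arm_expected_loss
#' @param thresholds numeric vector of clinical thresholds, default `c(5, 10)`.
#' @param level credible level for summaries.
#' @return an object of class `derived_draws`: list with matrix `draws`
#'   (one column per quantity), `summaries` (data.frame), and metadata.
#' @export
derive_quantities <- function(samples, weights = affiliation_weights(),
                              thresholds = c(5, 10), month = 24,
                              level = 0.95) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  weights <- affiliation_weights(unclass(weights))
  deltas <- arm_expected_loss(samples, weights, month)
  # contrasts are computed from the coefficient-vector difference, in
  # which the affiliation terms cancel exactly: the delta draws are
  # bit-identical under any valid weighting, not merely equal to rounding
  dm <- draw_matrix(samples, c("a000", paste0("beta", 1:10)))
  co1 <- arm_mean_coefficients(1L, month, weights)
  out <- list(Delta1 = deltas[, 1L], Delta2 = deltas[, 2L],
              Delta3 = deltas[, 3L],
              delta2 = drop(dm %*% (arm_mean_coefficients(2L, month, weights) - co1)),
              delta3 = drop(dm %*% (arm_mean_coefficients(3L, month, weights) - co1)))
  for (th in thresholds) {
    p <- matrix(NA_real_, nrow(deltas), 3L)
    for (arm in 1:3)
      p[, arm] <- threshold_probability(samples, weights, th, arm, month)
    nm <- paste0("p", th, "_arm", 1:3)
    for (j in 1:3) out[[nm[j]]] <- p[, j]
    out[[paste0("dp", th, "_2")]] <- p[, 2L] - p[, 1L]
    out[[paste0("dp", th, "_3")]] <- p[, 3L] - p[, 1L]
  }
  dr <- do.call(cbind, out)
  contrast_cols <- grep("^(delta|dp)", colnames(dr), value = TRUE)
  summaries <- do.call(rbind, lapply(colnames(dr), function(q) {
    ci <- credible_interval(dr[, q], level)
    data.frame(quantity = q, mean = ci$mean, sd = stats::sd(dr[, q]),
               ci_low = ci$lower, ci_high = ci$upper,
               prob_gt0 = if (q %in% contrast_cols)
                 exceedance_probability(dr[, q]) else NA_real_)
  }))
  structure(list(draws = dr, summaries = summaries,
                 thresholds = thresholds, month = month,
                 weights = unclass(weights), level = level,
                 variant = samples$variant),
            class = "derived_draws")
}

#' Arm contrasts and their exceedance probabilities
#'
#' @param derived a [derive_quantities()] result.
#' @return list with per-draw `delta2`, `delta3` and the exceedance
#'   probabilities `prob_gt0_2`, `prob_gt0_3` (fraction of draws strictly
#'   positive).
#' @export
arm_contrasts <- function(derived) {
  stopifnot(inherits(derived, "derived_draws"))
  d2 <- derived$draws[, "delta2"]
  d3 <- derived$draws[, "delta3"]
  list(delta2 = d2, delta3 = d3,
       prob_gt0_2 = exceedance_probability(d2),
       prob_gt0_3 = exceedance_probability(d3))
}

#' @export
print.derived_draws <- function(x, ...) {
  cat("derived_draws (", x$variant, "), month ", x$month, ", ",
      nrow(x$draws), " draws\n", sep = "")
  print(x$summaries, digits = 3)
  invisible(x)
}

#' Write derived summaries as JSON
#'
#' One JSON object per quantity: `{mean, sd, ci_low, ci_high, prob_gt0}`
#' (`prob_gt0` only where applicable).
#'
#' @param derived a `derived_draws` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_derived_json <- function(derived, path) {
  s <- derived$summaries
  keyed <- lapply(seq_len(nrow(s)), function(i) {
    rec <- list(mean = s$mean[i], sd = s$sd[i],
                ci_low = s$ci_low[i], ci_high = s$ci_high[i])
    if (!is.na(s$prob_gt0[i])) rec$prob_gt0 <- s$prob_gt0[i]
    rec
  })
  names(keyed) <- s$quantity
  jsonlite::write_json(keyed, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
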