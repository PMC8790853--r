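# Convergence diagnostics: classic split potential-scale-reduction and
# autocorrelation-based multi-chain effective sample size.

# accept either a posterior_draws object + parameter name, or a
# draws x chains matrix directly
as_chain_matrix <- function(x, parameter) {
  if (inherits(x, "posterior_draws")) {
    if (is.null(parameter)) stop("parameter must be named for posterior_draws input")
    chain_matrix(x, parameter)
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}

#' Split potential scale reduction factor (R-hat)
#'
#' Classic Gelman–Rubin statistic computed on split chains: each chain is
#' halved, and with `W` and `B` the within- and between-sequence variances
#' of the `2 * n_chains` half-sequences of length `n`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Returns 1 for a parameter with
#' zero total variance (constant chains). No rank-normalization or folding
#' is applied.
#'
#' @param x a `posterior_draws` object, or a draws-by-chains numeric matrix.
#' @param parameter parameter name when `x` is a `posterior_draws` object.
#' @return a single numeric value `>= 1` (up to numerical tolerance).
#' @export
split_rhat <- function(x, parameter = NULL) {
  m <- as_chain_matrix(x, parameter)
  if (nrow(m) < 2L) stop("split_rhat needs at least 2 draws per chain")
  sp <- split_chains(m)
  n <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    if (isTRUE(all.equal(B, 0)) || B == 0) return(1)
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# biased (1/n) autocovariance via FFT
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  M <- stats::nextn(2L * n)
  f <- stats::fft(c(x, numeric(M - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / M
  ac[seq_len(n)] / n
}

#' Multi-chain effective sample size
#'
#' Autocorrelation-based ESS combined across split chains: with `W`, `B`
#' and `var+ = (n-1)/n W + B/n` as in [split_rhat()], the combined
#' autocorrelations are `rho_t = 1 - (W - mean chain autocovariance_t) /
#' var+`, summed in Geyer pairs and truncated at the first negative paired
#' sum (initial positive sequence); `ESS = m * n / (1 + 2 * sum rho_t)`,
#' capped at the total number of draws. Constant chains have no
#' autocorrelation structure: the total draw count is returned with
#' attribute `constant = TRUE`.
#'
#' @inheritParams split_rhat
#' @return a single numeric ESS value.
#' @export
effective_sample_size <- function(x, parameter = NULL) {
  m <- as_chain_matrix(x, parameter)
  if (nrow(m) < 8L) stop("effective_sample_size needs at least 8 draws per chain")
  sp <- split_chains(m)
  n <- nrow(sp)
  nc <- ncol(sp)
  total <- n * nc
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) {
    out <- total
    attr(out, "constant") <- TRUE
    return(out)
  }
  B <- n * stats::var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B / n
  acov <- vapply(seq_len(nc), function(j) autocov_fft(sp[, j]), numeric(n))
  # unbias the /n autocovariances to match the n-1 denominator of W
  acov <- acov * n / (n - 1)
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0
  max_t <- n - 2L
  tau_sum <- 0
  t <- 0L
  while (t + 1L <= max_t) {
    pair <- rho[t + 1L] + rho[t + 2L]   # lags t and t+1
    if (pair <= 0) break
    tau_sum <- tau_sum + pair
    t <- t + 2L
  }
  tau <- max(-1 + 2 * tau_sum, 1 / 1e6)
  ess <- total / tau
  min(ess, total)
}

#' Convergence report for the monitored parameters
#'
#' R-hat and effective sample size for every monitored parameter
#' (intercept, the ten fixed effects and the scale parameters; the
#' random-effect deviates are excluded from the pass/fail gate), with pass
#' flags against the protocol thresholds `Rhat < 1.01` and `ESS > 400`.
#'
#' @param samples a `posterior_draws` object.
#' @param rhat_threshold,ess_threshold gate thresholds.
#' @return a data.frame of class `diagnostics_report` with columns
#'   `parameter`, `rhat`, `ess`, `rhat_ok`, `ess_ok`, and attribute
#'   `pass` (all gates met).
#' @export
diagnostics_report <- function(samples, rhat_threshold = 1.01,
                               ess_threshold = 400) {
  stopifnot(inherits(samples, "posterior_draws"))
  pars <- samples$monitored
  rhat <- vapply(pars, function(p) split_rhat(samples, p), numeric(1))
  ess <- vapply(pars, function(p) as.numeric(effective_sample_size(samples, p)),
                numeric(1))
  out <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    rhat_ok = rhat < rhat_threshold,
                    ess_ok = ess > ess_threshold,
                    row.names = NULL)
  attr(out, "pass") <- all(out$rhat_ok & out$ess_ok)
  attr(out, "thresholds") <- c(rhat = rhat_threshold, ess = ess_threshold)
  class(out) <- c("diagnostics_report", "data.frame")
  out
}

#' Write a diagnostics report as JSON keyed by parameter
#'
#' @param report a [diagnostics_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(report, path) {
  keyed <- lapply(seq_len(nrow(report)), function(i) {
    list(rhat = report$rhat[i], ess = report$ess[i],
         rhat_ok = report$rhat_ok[i], ess_ok = report$ess_ok[i])
  })
  names(keyed) <- report$parameter
  keyed$overall_pass <- attr(report, "pass")
  jsonlite::write_json(keyed, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
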