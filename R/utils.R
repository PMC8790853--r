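# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Sum a vector within integer groups 1..k, returning a dense length-k vector
# even when some groups are unobserved.
#' @keywords internal
#' @noRd
group_sums <- function(x, idx, k) {
  out <- numeric(k)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Draw from N(mean, sd^2) truncated to (0, Inf). Inverse-CDF in the easy
# regime; shifted-exponential rejection (Robert 1995) deep in the upper tail
# where pnorm underflows.
#' @keywords internal
#' @noRd
rtnorm_pos <- function(mean, sd) {
  a <- -mean / sd
  if (a < 5) {
    lo <- stats::pnorm(a)
    u <- stats::runif(1L, lo, 1)
    x <- mean + sd * stats::qnorm(u)
    if (is.finite(x) && x > 0) return(x)
  }
  alpha <- (a + sqrt(a^2 + 4)) / 2
  repeat {
    z <- a + stats::rexp(1L, rate = alpha)
    if (stats::runif(1L) <= exp(-(z - alpha)^2 / 2)) return(mean + sd * z)
  }
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
#' @keywords internal
#' @noRd
slice_sample1 <- function(x0, logf, w = 1, m = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a point with non-finite density")
  z <- f0 - stats::rexp(1L)
  u <- stats::runif(1L)
  L <- x0 - w * u
  R <- L + w
  j <- floor(m * stats::runif(1L))
  k <- m - 1L - j
  while (j > 0 && logf(L) > z) {
    L <- L - w
    j <- j - 1L
  }
  while (k > 0 && logf(R) > z) {
    R <- R + w
    k <- k - 1L
  }
  repeat {
    x1 <- stats::runif(1L, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
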