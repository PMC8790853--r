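#' Sampler configuration
#'
#' The default protocol runs four parallel chains, each with 3000 warm-up
#' iterations discarded and 3000 retained draws. Fixed effects are
#' initialized from `N(0, init_scale^2)` and standard deviations from
#' half-`N(0, 1)` (the improper flat fixed-effect prior cannot be sampled
#' from, so initialization is overdispersed but proper by construction).
#'
#' @param n_chains,n_warmup,n_keep positive counts.
#' @param seed integer; every chain derives its own stream from it.
#' @param init_scale positive SD of the fixed-effect initialization.
#' @param fix optional named list clamping scale parameters instead of
#'   sampling them, e.g. `list(sigma = 3.92, sigma_eta = 0)`. Clamping a
#'   level SD at 0 removes that level (its effects are held at zero); this
#'   is how the degenerate ordinary-regression limit used by the
#'   conjugate oracle tests is reached.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_warmup = 3000L, n_keep = 3000L,
                           seed = 1L, init_scale = 5, fix = list()) {
  if (n_chains < 1L || n_warmup < 1L || n_keep < 1L)
    stop("n_chains, n_warmup and n_keep must all be >= 1")
  if (init_scale <= 0) stop("init_scale must be positive")
  allowed <- c("sigma", "sigma_gamma", "sigma_eta", "sigma_theta")
  if (length(fix)) {
    if (!all(names(fix) %in% allowed))
      stop("fix may only name ", paste(allowed, collapse = ", "))
    if (!all(vapply(fix, function(v) is.numeric(v) && length(v) == 1L &&
                      is.finite(v) && v >= 0, logical(1))))
      stop("fix values must be single finite nonnegative numbers")
    if (!is.null(fix$sigma) && fix$sigma <= 0)
      stop("sigma cannot be fixed at 0")
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_keep = as.integer(n_keep),
                 seed = as.integer(seed),
                 init_scale = init_scale, fix = fix),
            class = "sampler_config")
}

monitored_parameters <- function(variant) {
  c("a000", paste0("beta", 1:10), "sigma", "sigma_gamma", "sigma_eta",
    if (variant == "model2") "sigma_theta")
}

#' Draw posterior samples by blocked Gibbs sampling
#'
#' Markov chain Monte Carlo for the three- and four-level hierarchical
#' models. The scan works on the marginal posterior of the fixed effects
#' and the four scale parameters, with every random-effect level
#' integrated out of both kinds of update: the marginal covariance
#' `sigma^2 I + sigma_gamma^2 Zp Zp' + sigma_theta^2 Zg Zg' +
#' sigma_eta^2 Zs Zs'` is inverted analytically by nested Woodbury
#' identities (the patient-in-group-in-site nesting makes every correction
#' diagonal), so the fixed effects are drawn from their exact Gaussian
#' marginal conditional and each scale is slice-sampled on the log scale
#' under the marginal likelihood. The site, group and patient intercepts
#' are then drawn once per sweep, top-down from their partially
#' marginalized conditionals — an exact draw from their joint conditional
#' given the retained parameters. Integrating the deviates out of every
#' update removes the funnel-shaped coupling between a scale and its
#' effects that makes naive centered Gibbs scans mix slowly.
#'
#' @param design a [build_design()] structure (carries the outcome).
#' @param priors a [prior_spec()].
#' @param variant model variant; defaults to the design's.
#' @param config a [sampler_config()].
#' @return an object of class `posterior_draws`: an array `draws` indexed
#'   (chain, draw, parameter) holding the monitored parameters
#'   (`a000`, `beta1..beta10`, the SDs) and every random-effect deviate
#'   (`eta[i]`, `theta[k]`, `gamma[j]`), plus metadata.
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             variant = design$variant,
                             config = sampler_config()) {
  stopifnot(inherits(design, "design_structure"))
  if (!variant %in% c("model1", "model2")) stop("unknown variant: ", variant)
  X <- design$X
  y <- design$y
  n <- length(y)
  p <- ncol(X)
  site <- design$site
  patient <- design$patient
  group <- design$group
  S <- design$n_sites
  P <- design$n_patients
  G <- if (variant == "model2") design$n_groups else 0L
  gpos <- group > 0L
  cnt_site <- tabulate(site, S)
  cnt_pat <- tabulate(patient, P)
  cnt_grp <- if (G > 0L) tabulate(group[gpos], G) else integer(0)
  scale2 <- priors$sd_prior_scale^2
  fix <- config$fix

  par_names <- c(monitored_parameters(variant),
                 paste0("eta[", seq_len(S), "]"),
                 if (G > 0L) paste0("theta[", seq_len(G), "]"),
                 paste0("gamma[", seq_len(P), "]"))
  n_par <- length(par_names)
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_keep, n_par),
                 dimnames = list(NULL, NULL, par_names))

  sd_fixed <- function(name) !is.null(fix[[name]])
  sd_value <- function(name, random) {
    if (sd_fixed(name)) fix[[name]] else random()
  }

  for (chain in seq_len(config$n_chains)) {
    set.seed((abs(config$seed) %% 1000003L) * 1009L + chain)

    # overdispersed but proper initialization; bounded retries on the
    # (theoretically unreachable) non-finite case
    for (attempt in 1:20) {
      b <- rnorm(p, 0, config$init_scale)
      sigma <- sd_value("sigma", function() abs(rnorm(1)) + 1e-3)
      s_eta <- sd_value("sigma_eta", function() abs(rnorm(1)) + 1e-3)
      s_gam <- sd_value("sigma_gamma", function() abs(rnorm(1)) + 1e-3)
      s_the <- if (G > 0L) sd_value("sigma_theta", function() abs(rnorm(1)) + 1e-3) else 0
      eta <- if (s_eta > 0) rnorm(S, 0, s_eta) else numeric(S)
      gam <- if (s_gam > 0) rnorm(P, 0, s_gam) else numeric(P)
      the <- if (G > 0L && s_the > 0) rnorm(G, 0, s_the) else numeric(G)
      if (is.finite(sigma) && sigma > 0) break
      if (attempt == 20L)
        stop("initialization produced a non-finite log posterior after 20 retries")
    }

    eta_obs <- eta[site]
    gam_obs <- gam[patient]
    the_obs <- numeric(n)
    if (G > 0L) the_obs[gpos] <- the[group[gpos]]

    # nesting maps for the marginalized location update
    site_of_patient <- site[match(seq_len(P), patient)]
    group_of_patient <- if (G > 0L) {
      gp <- integer(P)
      gp[patient[gpos]] <- group[gpos]
      gp
    } else integer(P)
    site_of_group <- if (G > 0L) site[match(seq_len(G), group)] else integer(0)
    dense_rowsum <- function(M, idx, K) {
      out <- matrix(0, K, ncol(M))
      s <- rowsum(M, idx)
      out[as.integer(rownames(s)), ] <- s
      out
    }

    gp_pos <- group_of_patient > 0L

    # Woodbury scalars and log-determinant of the marginal covariance
    # V = sigma^2 I + s_gam^2 Zp Zp' + s_the^2 Zg Zg' + s_eta^2 Zs Zs';
    # the nesting makes every correction diagonal.
    wb_make <- function(sigma, s_gam, s_the, s_eta) {
      cgam <- if (s_gam > 0) s_gam^2 / (sigma^2 + cnt_pat * s_gam^2) else numeric(P)
      np2c <- cnt_pat^2 * cgam
      grp_active <- G > 0L && s_the > 0
      t_g <- d_g <- numeric(0)
      ld <- 2 * n * log(sigma)
      if (s_gam > 0) ld <- ld + sum(log1p(cnt_pat * s_gam^2 / sigma^2))
      if (grp_active) {
        np2c_g <- group_sums(np2c[gp_pos], group_of_patient[gp_pos], G)
        t_g <- (cnt_grp - np2c_g) / sigma^2
        d_g <- 1 / (1 / s_the^2 + t_g)
        ld <- ld + sum(log1p(s_the^2 * t_g))
      }
      eta_active <- s_eta > 0
      e_s <- numeric(0)
      if (eta_active) {
        np2c_s <- group_sums(np2c, site_of_patient, S)
        u_s <- (cnt_site - np2c_s) / sigma^2
        if (grp_active)
          u_s <- u_s - group_sums(t_g^2 * d_g, site_of_group, S)
        e_s <- 1 / (1 / s_eta^2 + u_s)
        ld <- ld + sum(log1p(s_eta^2 * u_s))
      }
      list(sigma2 = sigma^2, cgam = cgam, gam_active = s_gam > 0,
           grp_active = grp_active, d_g = d_g,
           eta_active = eta_active, e_s = e_s, logdet = ld)
    }
    solveB <- function(M, wb) {
      if (wb$gam_active)
        M <- M - (wb$cgam * dense_rowsum(M, patient, P))[patient, , drop = FALSE]
      M / wb$sigma2
    }
    solveA <- function(M, wb) {
      W <- solveB(M, wb)
      if (wb$grp_active) {
        GS <- dense_rowsum(W[gpos, , drop = FALSE], group[gpos], G)
        C <- matrix(0, n, ncol(M))
        C[gpos, ] <- (wb$d_g * GS)[group[gpos], , drop = FALSE]
        W <- W - solveB(C, wb)
      }
      W
    }
    solveV <- function(M, wb) {
      W <- solveA(M, wb)
      if (wb$eta_active) {
        SS <- dense_rowsum(W, site, S)
        W <- W - solveA((wb$e_s * SS)[site, , drop = FALSE], wb)
      }
      W
    }
    # log N(r | 0, V) up to a constant, for the scale updates. Because r
    # is held fixed across all slice evaluations of a sweep, the quadratic
    # form reduces to per-patient / per-group / per-site sufficient
    # statistics of r, making each evaluation O(P + G + S) rather than O(n).
    marg_loglik_maker <- function(r) {
      SS_tot <- sum(r^2)
      psum <- group_sums(r, patient, P)
      gsum <- if (G > 0L) group_sums(psum[gp_pos], group_of_patient[gp_pos], G)
      ssum <- group_sums(psum, site_of_patient, S)
      function(sigma, s_gam, s_the, s_eta) {
        s2 <- sigma^2
        ld <- 2 * n * log(sigma)
        if (s_gam > 0) {
          cgam <- s_gam^2 / (s2 + cnt_pat * s_gam^2)
          ld <- ld + sum(log1p(cnt_pat * s_gam^2 / s2))
          rBr <- (SS_tot - sum(cgam * psum^2)) / s2
          bp <- cgam * cnt_pat * psum
          np2c <- cnt_pat^2 * cgam
        } else {
          rBr <- SS_tot / s2
          bp <- np2c <- numeric(P)
        }
        rQr <- rBr
        grp_active <- G > 0L && s_the > 0
        if (grp_active) {
          gB <- (gsum - group_sums(bp[gp_pos], group_of_patient[gp_pos], G)) / s2
          t_g <- (cnt_grp - group_sums(np2c[gp_pos], group_of_patient[gp_pos], G)) / s2
          d_g <- 1 / (1 / s_the^2 + t_g)
          ld <- ld + sum(log1p(s_the^2 * t_g))
          rQr <- rQr - sum(d_g * gB^2)
        }
        if (s_eta > 0) {
          sB <- (ssum - group_sums(bp, site_of_patient, S)) / s2
          u_s <- (cnt_site - group_sums(np2c, site_of_patient, S)) / s2
          if (grp_active) {
            sA <- sB - group_sums(t_g * d_g * gB, site_of_group, S)
            u_s <- u_s - group_sums(t_g^2 * d_g, site_of_group, S)
          } else sA <- sB
          e_s <- 1 / (1 / s_eta^2 + u_s)
          ld <- ld + sum(log1p(s_eta^2 * u_s))
          rQr <- rQr - sum(e_s * sA^2)
        }
        -0.5 * (ld + rQr)
      }
    }

    total_iter <- config$n_warmup + config$n_keep
    for (it in seq_len(total_iter)) {
      ## fixed effects: conditional with all random effects integrated out
      wb <- wb_make(sigma, s_gam, s_the, s_eta)
      ViXy <- solveV(cbind(X, y), wb)
      Prec <- crossprod(X, ViXy[, seq_len(p), drop = FALSE])
      Rc <- tryCatch(chol((Prec + t(Prec)) / 2), error = function(e)
        stop("fixed-effect design is rank-deficient for these data ",
             "(collinear or empty predictor columns); the flat prior ",
             "makes the posterior improper", call. = FALSE))
      bhat <- backsolve(Rc, backsolve(Rc, crossprod(X, ViXy[, p + 1L]),
                                      transpose = TRUE))
      b <- drop(bhat) + backsolve(Rc, rnorm(p))
      fit <- drop(X %*% b)
      r <- y - fit

      ## scales: slice-sample each on the log scale from its conditional
      ## given the fixed effects only (ALL random-effect levels integrated
      ## out) — no funnel between a scale and the deviates it governs
      mll <- marg_loglik_maker(r)
      if (!sd_fixed("sigma")) {
        sigma <- exp(slice_sample1(log(sigma), function(u) {
          s <- exp(u)
          mll(s, s_gam, s_the, s_eta) + u - s^2 / (2 * scale2)
        }))
      }
      if (s_gam > 0 && !sd_fixed("sigma_gamma")) {
        s_gam <- exp(slice_sample1(log(s_gam), function(u) {
          s <- exp(u)
          mll(sigma, s, s_the, s_eta) + u - s^2 / (2 * scale2)
        }))
      }
      if (G > 0L && s_the > 0 && !sd_fixed("sigma_theta")) {
        s_the <- exp(slice_sample1(log(s_the), function(u) {
          s <- exp(u)
          mll(sigma, s_gam, s, s_eta) + u - s^2 / (2 * scale2)
        }))
      }
      if (s_eta > 0 && !sd_fixed("sigma_eta")) {
        s_eta <- exp(slice_sample1(log(s_eta), function(u) {
          s <- exp(u)
          mll(sigma, s_gam, s_the, s) + u - s^2 / (2 * scale2)
        }))
      }

      ## random effects: one exact top-down draw given (b, scales) —
      ## site intercepts marginal over group and patient levels, group
      ## intercepts marginal over the patient level, patient intercepts
      ## from their full conditional
      wb <- wb_make(sigma, s_gam, s_the, s_eta)
      if (wb$eta_active) {
        Ar <- solveA(cbind(r), wb)
        m <- wb$e_s * drop(dense_rowsum(Ar, site, S))
        eta <- m + sqrt(wb$e_s) * rnorm(S)
        eta_obs <- eta[site]
      }
      if (wb$grp_active) {
        Br <- solveB(cbind(r - eta_obs), wb)
        m <- wb$d_g * drop(dense_rowsum(Br[gpos, , drop = FALSE], group[gpos], G))
        the <- m + sqrt(wb$d_g) * rnorm(G)
        the_obs[gpos] <- the[group[gpos]]
      }
      if (wb$gam_active) {
        r3 <- r - eta_obs - the_obs
        prec <- cnt_pat / sigma^2 + 1 / s_gam^2
        m <- (group_sums(r3, patient, P) / sigma^2) / prec
        gam <- m + rnorm(P) / sqrt(prec)
        gam_obs <- gam[patient]
      }

      if (it > config$n_warmup) {
        keep <- it - config$n_warmup
        draws[chain, keep, ] <- c(b, sigma, s_gam, s_eta,
                                  if (variant == "model2") s_the,
                                  eta, if (G > 0L) the, gam)
      }
    }
  }

  structure(
    list(draws = draws,
         parameters = par_names,
         monitored = monitored_parameters(variant),
         variant = variant,
         n_sites = S, n_groups = G, n_patients = P,
         seed = config$seed,
         n_chains = config$n_chains, n_keep = config$n_keep),
    class = "posterior_draws"
  )
}

#' Flatten posterior draws to a matrix
#'
#' @param samples a `posterior_draws` object.
#' @param parameters character vector of parameter names (default: the
#'   monitored set).
#' @return matrix with one row per retained draw (chains stacked) and one
#'   named column per parameter.
#' @export
draw_matrix <- function(samples, parameters = samples$monitored) {
  missing_p <- setdiff(parameters, samples$parameters)
  if (length(missing_p))
    stop("parameter(s) not in the registry: ", paste(missing_p, collapse = ", "))
  out <- sapply(parameters, function(p) as.vector(t(samples$draws[, , p])),
                simplify = FALSE)
  do.call(cbind, out)
}

# draws x chains matrix for one parameter
chain_matrix <- function(samples, parameter) {
  if (!parameter %in% samples$parameters)
    stop("parameter not in the registry: ", parameter)
  t(samples$draws[, , parameter, drop = TRUE])
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws (", x$variant, "): ",
      x$n_chains, " chains x ", x$n_keep, " draws, ",
      length(x$parameters), " parameters (",
      length(x$monitored), " monitored)\n", sep = "")
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, SD and central credible-interval bounds for the monitored
#' parameters, in the layout of the standard reporting tables (parameter,
#' mean, sd, 2.5%, 97.5%).
#'
#' @param object a `posterior_draws` object.
#' @param level credible level, default 0.95.
#' @param ... unused.
#' @return a data.frame with one row per monitored parameter.
#' @export
summary.posterior_draws <- function(object, level = 0.95, ...) {
  dm <- draw_matrix(object)
  lo <- (1 - level) / 2
  data.frame(
    parameter = colnames(dm),
    mean = colMeans(dm),
    sd = apply(dm, 2, stats::sd),
    lower = apply(dm, 2, stats::quantile, probs = lo, type = 7),
    upper = apply(dm, 2, stats::quantile, probs = 1 - lo, type = 7),
    row.names = NULL
  )
}

#' Write / read retained draws as CSV
#'
#' Columnar text: columns `chain`, `draw`, then one column per monitored
#' parameter.
#'
#' @param samples a `posterior_draws` object.
#' @param path file path.
#' @param parameters which parameters to write (default: monitored).
#' @return `write_draws_csv()` returns `path` invisibly;
#'   `read_draws_csv()` returns a data.frame.
#' @export
write_draws_csv <- function(samples, path, parameters = samples$monitored) {
  dm <- draw_matrix(samples, parameters)
  out <- data.frame(
    chain = rep(seq_len(samples$n_chains), each = samples$n_keep),
    draw = rep(seq_len(samples$n_keep), times = samples$n_chains)
  )
  out <- cbind(out, as.data.frame(dm))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @export
read_draws_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
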