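# End-to-end pipeline: simulate (or load) data, fit one or both model
# variants, derive the posterior quantities, compare the models, and write
# the report bundle.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Any section may be given as a
#' plain list; omitted fields fall back to the documented defaults of the
#' underlying constructors. A configuration can also be read from a YAML
#' file with [read_pipeline_config()]; command-line style overrides are
#' plain list elements.
#'
#' @param generator list of [generator_config()] arguments (ignored when
#'   `data_file` is given).
#' @param data_file optional path to an existing observation CSV.
#' @param models character vector of variants to fit, subset of
#'   `c("model1", "model2")`.
#' @param sd_prior_scale half-normal prior scale for the SDs.
#' @param sampler list of [sampler_config()] arguments.
#' @param thresholds clinical thresholds (percent), default `c(5, 10)`.
#' @param weights affiliation weights, default equal.
#' @param month reporting month, default 24.
#' @param compare run the WAIC / PSIS-LOO comparison when both models are
#'   fitted (default `TRUE`).
#' @param gate fail (with a condition of class `convergence_gate_failure`)
#'   when any monitored parameter has `Rhat >= 1.01` or `ESS <= 400`;
#'   default `TRUE`.
#' @param figures also write density figures (PNG) for the contrast
#'   quantities; default `FALSE`.
#' @param out_dir output directory, created if missing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), data_file = NULL,
                            models = c("model1", "model2"),
                            sd_prior_scale = 10, sampler = list(),
                            thresholds = c(5, 10),
                            weights = c(1, 1, 1) / 3, month = 24,
                            compare = TRUE, gate = TRUE, figures = FALSE,
                            out_dir = "bhmtrial-output") {
  bad <- setdiff(models, c("model1", "model2"))
  if (length(bad)) stop("unknown model variant(s): ", paste(bad, collapse = ", "))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(list(generator = generator, data_file = data_file,
                 models = models, sd_prior_scale = sd_prior_scale,
                 sampler = sampler, thresholds = thresholds,
                 weights = affiliation_weights(weights), month = month,
                 compare = isTRUE(compare), gate = isTRUE(gate),
                 figures = isTRUE(figures), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the sections above.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

pipeline_msg <- function(quiet, ...) if (!quiet) message(...)

plot_contrast_density <- function(draws, label, path) {
  grDevices::png(path, width = 900, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  grid <- seq(min(draws), max(draws), length.out = 512)
  kd <- kde_curve(draws, grid)
  graphics::plot(kd$grid, kd$density, type = "l", xlab = label,
                 ylab = "posterior density", main = label)
  pos <- kd$grid > 0
  if (any(pos))
    graphics::polygon(c(kd$grid[pos], rev(kd$grid[pos])),
                      c(kd$density[pos], numeric(sum(pos))),
                      col = "grey80", border = NA)
  graphics::lines(kd$grid, kd$density)
  graphics::abline(v = 0, lty = 2)
}

write_summary_table <- function(fits, path) {
  lines <- character(0)
  for (variant in names(fits)) {
    s <- summary(fits[[variant]])
    lines <- c(lines,
               sprintf("== %s ==", variant),
               sprintf("%-14s %10s %10s %10s %10s",
                       "parameter", "mean", "sd", "2.5%", "97.5%"),
               sprintf("%-14s %10.3f %10.3f %10.3f %10.3f",
                       s$parameter, s$mean, s$sd, s$lower, s$upper),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic trial from the generator section, or
#' load `data_file`, and write `data.csv`; (2) fit each requested model
#' variant, writing `draws_<model>.csv` and `diagnostics_<model>.json`,
#' and checking the convergence gate; (3) derive the posterior quantities
#' (`derived_<model>.json`, density-curve CSVs for the arm contrasts);
#' (4) when both models were fitted and comparison is enabled, write
#' `comparison.json` with WAIC and PSIS-LOO; (5) write `summary.txt`, the
#' parameter table (mean, sd, 2.5%, 97.5%) in the usual reporting layout.
#'
#' @param config a [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fitted objects, derived quantities,
#'   diagnostics, comparison (or `NULL`) and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$data_file)) {
    pipeline_msg(quiet, "reading observation table: ", config$data_file)
    table <- read_trial_table(config$data_file)
  } else {
    gcfg <- do.call(generator_config, config$generator)
    pipeline_msg(quiet, "simulating trial (seed ", gcfg$seed, ")")
    table <- generate_trial(gcfg)$table
  }
  paths$data <- file.path(config$out_dir, "data.csv")
  write_trial_table(table, paths$data)

  priors <- prior_spec(config$sd_prior_scale)
  scfg <- do.call(sampler_config, config$sampler)
  fits <- list()
  diagnostics <- list()
  logliks <- list()
  derived <- list()
  for (variant in config$models) {
    design <- build_design(table, variant)
    pipeline_msg(quiet, "fitting ", variant, " (", length(design$y),
                 " observations, seed ", scfg$seed, ")")
    fit <- sample_posterior(design, priors, variant, scfg)
    fits[[variant]] <- fit
    paths[[paste0("draws_", variant)]] <-
      file.path(config$out_dir, paste0("draws_", variant, ".csv"))
    write_draws_csv(fit, paths[[paste0("draws_", variant)]])

    rep <- diagnostics_report(fit)
    diagnostics[[variant]] <- rep
    paths[[paste0("diagnostics_", variant)]] <-
      file.path(config$out_dir, paste0("diagnostics_", variant, ".json"))
    write_diagnostics_json(rep, paths[[paste0("diagnostics_", variant)]])
    if (config$gate && !isTRUE(attr(rep, "pass"))) {
      bad <- rep$parameter[!(rep$rhat_ok & rep$ess_ok)]
      stop(structure(class = c("convergence_gate_failure", "error", "condition"),
                     list(message = paste0(variant,
                            " failed the convergence gate (Rhat >= 1.01 or ESS <= 400) for: ",
                            paste(bad, collapse = ", ")),
                          call = sys.call())))
    }

    dq <- derive_quantities(fit, config$weights, config$thresholds,
                            config$month)
    derived[[variant]] <- dq
    paths[[paste0("derived_", variant)]] <-
      file.path(config$out_dir, paste0("derived_", variant, ".json"))
    write_derived_json(dq, paths[[paste0("derived_", variant)]])

    for (q in c("delta2", "delta3", "Delta1", "Delta2", "Delta3")) {
      dr <- dq$draws[, q]
      grid <- seq(min(dr), max(dr), length.out = 512)
      dens_path <- file.path(config$out_dir,
                             paste0("density_", q, "_", variant, ".csv"))
      utils::write.csv(kde_curve(dr, grid), dens_path, row.names = FALSE)
      paths[[paste0("density_", q, "_", variant)]] <- dens_path
    }
    if (config$figures) {
      for (q in c("delta2", "delta3")) {
        fig_path <- file.path(config$out_dir,
                              paste0("figure_", q, "_", variant, ".png"))
        plot_contrast_density(dq$draws[, q], q, fig_path)
        paths[[paste0("figure_", q, "_", variant)]] <- fig_path
      }
    }
    logliks[[variant]] <- loglik_matrix(fit, design)
  }

  comparison <- NULL
  if (config$compare && all(c("model1", "model2") %in% names(fits))) {
    pipeline_msg(quiet, "comparing model1 vs model2 (WAIC, PSIS-LOO)")
    loo1 <- psis_loo(logliks$model1)
    loo2 <- psis_loo(logliks$model2)
    waic1 <- waic(logliks$model1)
    waic2 <- waic(logliks$model2)
    paths$comparison <- file.path(config$out_dir, "comparison.json")
    write_comparison_json(loo1, loo2, waic1, waic2, paths$comparison)
    comparison <- list(loo = list(model1 = loo1, model2 = loo2,
                                  diff = compare_models(loo1, loo2)),
                       waic = list(model1 = waic1, model2 = waic2,
                                   diff = compare_models(waic1, waic2)))
  }

  paths$summary <- file.path(config$out_dir, "summary.txt")
  write_summary_table(fits, paths$summary)
  pipeline_msg(quiet, "report bundle written to ", config$out_dir)

  invisible(list(table = table, fits = fits, diagnostics = diagnostics,
                 derived = derived, comparison = comparison, paths = paths))
}
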