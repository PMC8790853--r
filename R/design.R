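#' Build the fixed-effect design and grouping structure
#'
#' Translates a long-format observation table into the design used by the
#' likelihood and the sampler. The 11 fixed-effect columns follow the
#' reporting convention of the analysis tables:
#' intercept, `x1` (in-clinic group arm), `x2` (phone group arm), `t18`,
#' `t24`, `x1_t18`, `x2_t18`, `x1_t24`, `x2_t24`, `x3` (affiliation A2),
#' `x4` (affiliation A3). The individual-visit arm at month 6 in
#' affiliation A1 is the reference cell: all predictors zero. Row order of
#' the table is preserved.
#'
#' @param table a valid observation table (see [validate_trial_table()]).
#' @param variant `"model1"` (three-level: site, patient, residual) or
#'   `"model2"` (adds the partially nested intervention-group level).
#' @return an object of class `design_structure`: list with the model
#'   matrix `X`, outcome `y`, per-row integer indices `site`, `group`
#'   (0 for individual-arm rows), `patient`, level counts, and the variant.
#' @export
build_design <- function(table, variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  table <- validate_trial_table(table)
  x1 <- as.numeric(table$arm == "inclinic_group")
  x2 <- as.numeric(table$arm == "phone_group")
  t18 <- as.numeric(table$visit_month == 18L)
  t24 <- as.numeric(table$visit_month == 24L)
  x3 <- as.numeric(table$affiliation == "A2")
  x4 <- as.numeric(table$affiliation == "A3")
  X <- cbind(intercept = 1, x1 = x1, x2 = x2, t18 = t18, t24 = t24,
             x1_t18 = x1 * t18, x2_t18 = x2 * t18,
             x1_t24 = x1 * t24, x2_t24 = x2 * t24,
             x3 = x3, x4 = x4)

  site_levels <- sort(unique(table$site_id))
  patient_levels <- sort(unique(table$patient_id))
  group_levels <- sort(unique(table$group_id[table$group_id > 0L]))
  site <- match(table$site_id, site_levels)
  patient <- match(table$patient_id, patient_levels)
  group <- integer(nrow(table))
  pos <- table$group_id > 0L
  group[pos] <- match(table$group_id[pos], group_levels)

  structure(
    list(X = X, y = table$pct_weight_loss,
         site = site, group = group, patient = patient,
         n_sites = length(site_levels),
         n_groups = length(group_levels),
         n_patients = length(patient_levels),
         site_levels = site_levels, group_levels = group_levels,
         patient_levels = patient_levels,
         arm = table$arm, visit_month = table$visit_month,
         variant = variant),
    class = "design_structure"
  )
}

#' @export
print.design_structure <- function(x, ...) {
  cat("design_structure (", x$variant, "): ",
      length(x$y), " observations, ",
      x$n_sites, " sites, ",
      x$n_groups, " intervention groups, ",
      x$n_patients, " patients\n", sep = "")
  invisible(x)
}
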