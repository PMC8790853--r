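#' @importFrom stats rnorm runif
NULL

#' Arm and affiliation labels
#'
#' The three care-delivery arms of the trial design: in-clinic individual
#' visits (the reference arm, no intervention group), in-clinic group visits,
#' and phone-based group visits. Affiliations are the three recruiting
#' academic centers, coded `A1` (reference), `A2`, `A3`.
#'
#' @name trial_labels
#' @keywords internal
trial_arms <- c("individual", "inclinic_group", "phone_group")

#' @rdname trial_labels
#' @keywords internal
trial_affiliations <- c("A1", "A2", "A3")

default_true_fixed <- function() {
  c(a000 = 6.24,
    beta1 = 2.67, beta2 = 1.98, beta3 = -2.26, beta4 = -3.05,
    beta5 = 0.06, beta6 = -2.16, beta7 = -0.41, beta8 = -0.10,
    beta9 = -0.83, beta10 = -0.51)
}

default_true_sds <- function() {
  c(sigma = 3.92, sigma_gamma = 6.66, sigma_eta = 0.98, sigma_theta = 1.28)
}

#' Configuration for the synthetic trial generator
#'
#' Describes a three-arm cluster-randomized weight-loss trial: sites are
#' randomized to arms in equal numbers, each site belongs to one of three
#' affiliations, participants in the two group-based arms are partitioned
#' into intervention groups, and percent weight loss is observed at a fixed
#' set of post-baseline visits.
#'
#' The defaults emulate the study conditions the package is built around:
#' 36 sites split evenly over 3 affiliations and 3 arms, 39 patients per
#' site (1404 participants), intervention groups of 14, visits at months
#' 6, 18 and 24, and true effects/variance components set to the posterior
#' means of the four-level re-analysis (group-level SD 1.28).
#'
#' @param n_sites number of sites; must be divisible by 3 (equal
#'   randomization over the three arms).
#' @param patients_per_site a single count or a length-`n_sites` vector.
#' @param group_size target intervention-group size in the two group-based
#'   arms; within a site, patients are partitioned into consecutive blocks
#'   of this size (the last block may be smaller).
#' @param visit_months ordered vector of post-baseline visit months, a
#'   non-empty subset of `c(6, 18, 24)`.
#' @param true_fixed named vector with elements `a000`, `beta1`..`beta10`
#'   (percent weight loss scale).
#' @param true_sds named vector `sigma`, `sigma_gamma`, `sigma_eta`,
#'   `sigma_theta`, all `>= 0`. `sigma_theta = 0` switches the group-level
#'   variance component off.
#' @param dropout_rate probability in `[0, 1]` that any single visit row is
#'   missing, independently (missing completely at random); default 0.
#' @param seed integer RNG seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_sites = 36L,
                             patients_per_site = 39L,
                             group_size = 14L,
                             visit_months = c(6L, 18L, 24L),
                             true_fixed = default_true_fixed(),
                             true_sds = default_true_sds(),
                             dropout_rate = 0,
                             seed = 1L) {
  if (length(n_sites) != 1L || n_sites < 3L || n_sites %% 3L != 0L)
    stop("n_sites must be a positive multiple of 3 (equal randomization to the three arms)")
  if (any(patients_per_site < 1L))
    stop("patients_per_site must be >= 1")
  if (!length(patients_per_site) %in% c(1L, n_sites))
    stop("patients_per_site must be a scalar or one count per site")
  if (length(group_size) != 1L || group_size < 1L)
    stop("group_size must be >= 1")
  if (length(visit_months) == 0L || !all(visit_months %in% c(6, 18, 24)))
    stop("visit_months must be a non-empty subset of {6, 18, 24}")
  fixed_names <- names(default_true_fixed())
  if (!all(fixed_names %in% names(true_fixed)))
    stop("true_fixed must name a000 and beta1..beta10")
  sd_names <- names(default_true_sds())
  if (!all(sd_names %in% names(true_sds)))
    stop("true_sds must name sigma, sigma_gamma, sigma_eta, sigma_theta")
  if (any(true_sds[sd_names] < 0))
    stop("true_sds must all be >= 0")
  if (length(dropout_rate) != 1L || dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  structure(
    list(n_sites = as.integer(n_sites),
         patients_per_site = as.integer(rep_len(patients_per_site, n_sites)),
         group_size = as.integer(group_size),
         visit_months = as.integer(sort(unique(visit_months))),
         true_fixed = true_fixed[fixed_names],
         true_sds = true_sds[sd_names],
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic cluster-randomized weight-loss trial
#'
#' Runs the four-level hierarchical model forward: sites are assigned to
#' arms in equal blocks and to affiliations in rotation (so each arm holds
#' an equal number of sites from every affiliation); patients in the two
#' group-based arms are partitioned into intervention groups; and each
#' observed percent weight loss is
#' `a000 + fixed-effect linear predictor + eta_site + theta_group +
#' gamma_patient + eps`, with `eta ~ N(0, sigma_eta^2)`,
#' `theta ~ N(0, sigma_theta^2)` (group-based arms only; exactly zero in the
#' individual arm), `gamma ~ N(0, sigma_gamma^2)` and residual
#' `eps ~ N(0, sigma^2)`. Visits are then dropped independently with the
#' configured dropout probability.
#'
#' @param config a [generator_config()].
#' @return a list with elements `table` (the long-format observation
#'   data.frame, one row per participant-visit, columns
#'   `site_id, affiliation, arm, group_id, patient_id, visit_month,
#'   pct_weight_loss`) and `truth` (the generating parameter values and the
#'   realized `eta`, `theta`, `gamma` draws).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  S <- config$n_sites
  arm_of_site <- rep(trial_arms, each = S / 3L)
  affil_of_site <- rep_len(trial_affiliations, S)

  n_pat <- config$patients_per_site
  P <- sum(n_pat)
  site_of_patient <- rep.int(seq_len(S), n_pat)

  # consecutive blocks of group_size within each group-based-arm site
  group_of_patient <- integer(P)
  next_group <- 1L
  for (s in seq_len(S)) {
    if (arm_of_site[s] == "individual") next
    idx <- which(site_of_patient == s)
    blocks <- (seq_along(idx) - 1L) %/% config$group_size
    group_of_patient[idx] <- next_group + blocks
    next_group <- next_group + max(blocks) + 1L
  }
  G <- next_group - 1L

  sds <- config$true_sds
  eta <- rnorm(S, 0, sds[["sigma_eta"]])
  theta <- if (G > 0L) rnorm(G, 0, sds[["sigma_theta"]]) else numeric(0)
  gamma <- rnorm(P, 0, sds[["sigma_gamma"]])

  months <- config$visit_months
  nv <- length(months)
  pat <- rep(seq_len(P), each = nv)
  tab <- data.frame(
    site_id = site_of_patient[pat],
    affiliation = affil_of_site[site_of_patient[pat]],
    arm = arm_of_site[site_of_patient[pat]],
    group_id = group_of_patient[pat],
    patient_id = pat,
    visit_month = rep(months, times = P),
    pct_weight_loss = 0,
    stringsAsFactors = FALSE
  )

  fx <- config$true_fixed
  x1 <- as.numeric(tab$arm == "inclinic_group")
  x2 <- as.numeric(tab$arm == "phone_group")
  t18 <- as.numeric(tab$visit_month == 18L)
  t24 <- as.numeric(tab$visit_month == 24L)
  x3 <- as.numeric(tab$affiliation == "A2")
  x4 <- as.numeric(tab$affiliation == "A3")
  mu <- fx[["a000"]] +
    fx[["beta1"]] * x1 + fx[["beta2"]] * x2 +
    fx[["beta3"]] * t18 + fx[["beta4"]] * t24 +
    fx[["beta5"]] * x1 * t18 + fx[["beta6"]] * x2 * t18 +
    fx[["beta7"]] * x1 * t24 + fx[["beta8"]] * x2 * t24 +
    fx[["beta9"]] * x3 + fx[["beta10"]] * x4

  re <- eta[tab$site_id] + gamma[tab$patient_id]
  has_grp <- tab$group_id > 0L
  re[has_grp] <- re[has_grp] + theta[tab$group_id[has_grp]]
  tab$pct_weight_loss <- mu + re + rnorm(nrow(tab), 0, sds[["sigma"]])

  if (config$dropout_rate > 0) {
    keep <- runif(nrow(tab)) >= config$dropout_rate
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }

  truth <- list(true_fixed = fx, true_sds = sds,
                eta = eta, theta = theta, gamma = gamma,
                arm_of_site = arm_of_site, affil_of_site = affil_of_site,
                site_of_patient = site_of_patient,
                group_of_patient = group_of_patient)
  list(table = tab, truth = truth)
}

trial_table_columns <- c("site_id", "affiliation", "arm", "group_id",
                         "patient_id", "visit_month", "pct_weight_loss")

#' Validate a long-format trial observation table
#'
#' Checks the structural invariants of the long format: required columns,
#' known arm and affiliation labels, unique (patient, visit) pairs,
#' `group_id = 0` exactly for individual-arm rows, groups confined to a
#' single site and arm, and affiliation constant within site. Errors name
#' the offending column, label or row.
#'
#' @param table a data.frame in the long observation format.
#' @return the table, invisibly, with columns in canonical order.
#' @export
validate_trial_table <- function(table) {
  missing_cols <- setdiff(trial_table_columns, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  table <- table[trial_table_columns]
  bad_arm <- setdiff(unique(table$arm), trial_arms)
  if (length(bad_arm))
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "))
  bad_aff <- setdiff(unique(table$affiliation), trial_affiliations)
  if (length(bad_aff))
    stop("unknown affiliation label(s): ", paste(bad_aff, collapse = ", "))
  if (!all(table$visit_month %in% c(6L, 18L, 24L)))
    stop("visit_month must be one of 6, 18, 24")
  dup <- duplicated(table[c("patient_id", "visit_month")])
  if (any(dup))
    stop("duplicate (patient_id, visit_month) pair at row ", which(dup)[1L])
  ind <- table$arm == "individual"
  bad <- which(ind & table$group_id != 0L)
  if (length(bad))
    stop("row ", bad[1L], ": individual-arm row has nonzero group_id")
  bad <- which(!ind & table$group_id <= 0L)
  if (length(bad))
    stop("row ", bad[1L], ": group-based-arm row lacks a positive group_id")
  grp <- table[table$group_id > 0L, , drop = FALSE]
  if (nrow(grp)) {
    by_grp <- split(seq_len(nrow(grp)), grp$group_id)
    for (rows in by_grp) {
      if (length(unique(grp$site_id[rows])) > 1L ||
          length(unique(grp$arm[rows])) > 1L)
        stop("group ", grp$group_id[rows[1L]],
             " spans more than one site or arm")
    }
  }
  aff_per_site <- tapply(table$affiliation, table$site_id,
                         function(a) length(unique(a)))
  if (any(aff_per_site > 1L))
    stop("site ", names(aff_per_site)[which(aff_per_site > 1L)[1L]],
         " has more than one affiliation")
  invisible(table)
}

#' Read / write the long-format observation CSV
#'
#' The on-disk dialect is a plain comma-separated UTF-8 file with header
#' `site_id,affiliation,arm,group_id,patient_id,visit_month,pct_weight_loss`,
#' `.` as decimal separator, and the label sets documented in
#' [validate_trial_table()]. Reading validates the table and rejects
#' malformed files naming the violated invariant; a write-then-read
#' round-trip reproduces the table (outcome values to 12 significant
#' digits).
#'
#' @param path file path.
#' @param table a valid observation table.
#' @return `read_trial_table()` returns the validated data.frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(site_id = "integer",
                                        affiliation = "character",
                                        arm = "character",
                                        group_id = "integer",
                                        patient_id = "integer",
                                        visit_month = "integer",
                                        pct_weight_loss = "numeric"))
  tab <- validate_trial_table(tab)
  tab
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(table, path) {
  table <- validate_trial_table(table)
  table$pct_weight_loss <- signif(table$pct_weight_loss, 12)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
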