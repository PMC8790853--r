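---
title: "Hierarchical Bayesian models for partially nested weight-loss trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian models for partially nested weight-loss trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Behavioral weight-loss trials often randomize primary-care practices
(sites) rather than individual patients, and deliver the intervention to
some arms in groups: a three-arm design might compare individual in-clinic
counseling against in-clinic group visits and phone-based group visits. The
outcome — percent weight loss from baseline — is measured repeatedly (here
at months 6, 18 and 24). Three features complicate the analysis:

* **clustering by site** — patients in the same practice resemble each other;
* **partial nesting** — intervention groups exist only in the two
  group-based arms, so the group level applies to part of the data;
* **dual endpoints** — the field reports both the continuous outcome and
  the proportions achieving clinical 5% and 10% weight-loss thresholds.

`bhmtrial` implements a Bayesian workflow that handles all three with a
single model. Posterior draws of the model parameters are transformed into
every quantity of interest: arm means, arm contrasts, probabilities that
one arm beats another, and posterior-predictive probabilities of a new
patient crossing a clinical threshold — so the continuous and dichotomized
endpoints are harmonized instead of being fitted by separate models.

## The models

Let `y_ijt` be the percent weight loss of patient `j` in site `i` at visit
`t`. The **three-level model** (`model1`) is

```
y = a000 + b1*x1 + b2*x2 + b3*t18 + b4*t24
    + b5*x1*t18 + b6*x2*t18 + b7*x1*t24 + b8*x2*t24
    + b9*x3 + b10*x4
    + eta_site + gamma_patient + eps
```

with `x1, x2` the arm indicators (in-clinic group and phone group; the
individual arm is the reference), `t18, t24` the visit indicators (month 6
is the reference), `x3, x4` the affiliation indicators (`A1` is the
reference), and

```
eta_i   ~ N(0, sigma_eta^2)     site level
gamma_j ~ N(0, sigma_gamma^2)   patient level
eps     ~ N(0, sigma^2)         residual
```

The **four-level model** (`model2`) adds a partially nested intervention
group intercept `theta_k ~ N(0, sigma_theta^2)` for patients in the two
group-based arms; individual-arm patients have no group effect (`theta`
identically 0 for them). Priors are noninformative: improper flat priors on
the intercept and the ten regression coefficients, and half-normal `N+(0, 10)`
priors on all standard deviations (percent weight loss units; the scale 10
is far above any plausible SD for this outcome, and is configurable via
`prior_spec()`).

A note on coefficient labels: we index the interactions in reporting-table
order — `b5 = x1*t18`, `b6 = x2*t18`, `b7 = x1*t24`, `b8 = x2*t24` — so the
24-month arm contrasts are `delta2 = b1 + b7` and `delta3 = b2 + b8`.

## Derived quantities

All reporting happens on functions of the posterior draws.

* **Arm-level expected 24-month loss.** For arm 1,
  `Delta1 = a000 + b4 + w2*b9 + w3*b10` with affiliation weights `w`
  (default arithmetic average, `w = (1/3, 1/3, 1/3)`);
  `Delta2 = Delta1 + b1 + b7` and `Delta3 = Delta1 + b2 + b8`. Because
  `b9` and `b10` cancel in differences, the contrasts `delta2`, `delta3`
  are *identical draws* under any valid weighting — the package tests this
  as a bit-level identity.
* **Exceedance probabilities.** `P(delta > 0)` is estimated by the
  fraction of draws strictly greater than zero. Ties at exactly zero have
  probability zero under the continuous posterior; they count as
  non-exceeding.
* **Threshold probabilities.** A new patient in arm `a` has predictive
  distribution `N(Delta_a, sigma^2 + sigma_gamma^2 + sigma_eta^2)` given
  the parameters, so the probability of achieving at least 5% loss is
  `1 - Phi((5 - Delta_a)/sd_pred)`, evaluated per draw and then summarized.
  The classical definition of this integral covers only the three-level
  variance; under the four-level model we extend it generatively: a new
  group-arm patient
  is also assigned a new group, so `sigma_theta^2` enters `sd_pred` for
  arms 2 and 3 and not for arm 1.
* **Sign coupling.** Within one draw the predictive SD is shared across
  arms, so `Delta2 > Delta1` exactly when `p5_2 > p5_1` and `p10_2 > p10_1`.
  The exceedance probability of the threshold-probability contrast is
  therefore *identical* to that of the continuous contrast — the package
  asserts this as an identity rather than a numerical coincidence, which is
  the mechanism behind matching probabilities for continuous and
  dichotomized endpoints.
* **Intervals and curves.** Credible intervals are central, from the
  linear-interpolation empirical quantiles (`quantile(..., type = 7)`,
  2.5% and 97.5% by default). Density figures use a Gaussian kernel with
  Silverman's rule-of-thumb bandwidth.

## Sampling

`sample_posterior()` runs an authored blocked Gibbs sampler. The default
protocol is four chains, 3000 warm-up and 3000 retained iterations each,
with overdispersed initialization (fixed effects from `N(0, 5^2)`; the flat
prior cannot be sampled, so initialization is proper by construction, and
the scale parameters start from half-`N(0,1)`).

The scan works on the *marginal* posterior of the fixed effects and the
four scale parameters. Because patients nest in groups nest in sites, the
marginal covariance

```
V = sigma^2 I + sigma_gamma^2 Zp Zp' + sigma_theta^2 Zg Zg' + sigma_eta^2 Zs Zs'
```

can be inverted by nested Woodbury identities in which every correction is
diagonal, in O(n) per evaluation. Each sweep

1. draws the 11 fixed effects exactly from their Gaussian conditional with
   all random effects integrated out;
2. slice-samples each scale (log scale, stepping-out slice sampler) under
   the marginal likelihood of the residuals `y - Xb` — the per-unit
   sufficient statistics are precomputed once per sweep, so each slice
   evaluation costs O(#patients);
3. draws the site, group and patient intercepts top-down from their
   partially marginalized conditionals — one exact draw from the joint
   conditional of all random effects.

Integrating the random effects out of every update eliminates the
funnel-shaped coupling between a scale and its deviates (and between the
intercept/arm coefficients and the site effects) that makes naive centered
Gibbs scans mix slowly; in practice the retained draws behave close to
independently. The update of the location block jointly with an exact
redraw of the effects makes this a valid partially collapsed Gibbs scheme
whose stationary distribution is exactly the log-posterior defined by
`loglik_pointwise()` + `logprior()`.

Convergence is assessed by classic split potential-scale-reduction
(no rank normalization, matching the cited diagnostic) with the gate
`Rhat < 1.01`, and by autocorrelation-based multi-chain effective sample
size (Geyer initial-positive-sequence truncation) with the gate
`ESS > 400`, applied to the intercept, the ten coefficients and the scale
parameters; random-effect deviates are excluded from the gate.
`run_pipeline()` fails with a distinct condition class when a gate is
missed, unless gating is disabled.

## Model comparison

WAIC and PSIS-LOO operate on the conditional (observation-level) pointwise
log-likelihood evaluated at every retained draw, i.e. leave-one-observation-
out given all random effects — the default likelihood factorization of the
standard tooling for these criteria. The PSIS implementation follows the
reference recipe: tail size `M = ceiling(min(0.2 S, 3 sqrt(S)))`, a
generalized Pareto fitted to the tail ratios by a profile-likelihood point
estimate over a quantile-spaced shape grid, tail weights replaced by
expected order statistics of the fitted distribution, truncation at the raw
maximum, and the Pareto shape `k` reported per observation. A brute-force
`exact_loo_refit()` (guarded to 50 observations) refits the model once per
observation and serves as the oracle in the tests; when deleting an
observation removes its patient from the data, the patient effect is
integrated out analytically by widening the predictive variance. The
difference row follows the `model1 - model2` sign convention, with the
paired standard error computed from the pointwise elpd differences.

## The synthetic-trial generator

`generate_trial()` runs the four-level model forward. Defaults encode the
study conditions the package is built around: 36 sites in 3 affiliations
randomized equally to the 3 arms, 39 patients per site (1404 total,
matching the reported ~1407), intervention groups formed as consecutive
blocks of 14 within each group-arm site (the reported median group size),
visits at months 6/18/24, and generating values set to the published
posterior means (`a000 = 6.24`, ..., `sigma = 3.92`, `sigma_gamma = 6.66`,
`sigma_eta = 0.98`, `sigma_theta = 1.28`). Decisions taken where the study
description is silent:

* patients are allocated equally across sites (the per-site distribution is
  unpublished), overridable per site;
* sites are assigned to affiliations in rotation, which balances
  affiliations exactly within arms;
* missingness is visit-level and completely at random, default off — the
  study's missing-data pattern is unpublished;
* no baseline (month 0) rows are generated: the outcome is percent weight
  loss at the three post-baseline visits, exactly the quantity the model
  describes.

The generator emulates the statistical structure (variance components,
balanced design, group formation), not clinical features of real cohorts:
no informative dropout, no covariate imbalance, no skewness or outliers in
the outcome. Passing tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to real-data pathologies.

## Test design and problem sizes

The test-suite experiments are scaled-down versions of the full protocol,
chosen so each check retains statistical power:

* *Conjugate oracle*: with the level SDs clamped at 0 and `sigma` known,
  the exact posterior is `N(bhat_OLS, sigma^2 (X'X)^-1)`; a ~200-observation
  fixture and 2000 draws give 3-SE checks per coefficient.
* *Parameter recovery*: 12 sites × 20 patients (720 observations), truth at
  the published posterior means; 95% intervals must cover at least 12 of
  the 14 monitored parameters.
* *LOO oracle*: an 18-observation trial (6 sites, two per arm, one patient
  each, all three visits) keeps the n+1 refits cheap. Smaller designs —
  e.g. one site per arm, or a single visit — make the 11-column
  fixed-effect matrix rank-deficient, and under the flat prior the
  posterior is then improper; the sampler detects this and refuses.
* *Group-level detection*: 24 sites × 28 patients with groups of 14
  (2016 observations), 10 replicates per scenario. With
  `sigma_theta = 0` the WAIC difference should be within noise; with
  `sigma_theta = 3` the four-level model should win. The size was chosen
  because the conditional-likelihood WAIC contrast between these models is
  intrinsically weak — patient intercepts can absorb a group shift, so
  only the shrinkage error distinguishes the models — and smaller designs
  leave the sign of the difference dominated by Monte-Carlo noise.
* Generator moment checks compare level-mean variances against the
  *realized* variance of that level's draws (plus the known averaging
  correction): comparing against the nominal `sigma^2` would need tens of
  thousands of sites for the site level, since the sampling error of a
  variance over `S` units is of relative order `sqrt(2/S)`.

## Numerical choices and degenerate inputs

* Scales are sampled on the log scale; slice sampling is
  derivative-free and rejection-free, so no step-size tuning is exposed.
* `quantile(..., type = 7)` fixes the interval convention so printed
  intervals are reproducible to the last digit.
* Constant draw vectors: R-hat is defined as 1 (zero total variance), ESS
  is reported as the total draw count with a `constant` flag, and
  `kde_curve()` rejects them (zero bandwidth).
* PSIS with (numerically) constant ratios for an observation returns the
  plain importance estimate and flags the Pareto shape as not estimated.
* `exact_loo_refit()` seeds each refit deterministically from the
  configured seed and the held-out row, so the oracle is reproducible.
* Truncated-normal draws in the tools use inverse-CDF sampling with a
  rejection fallback deep in the tail.

## Known limitations

* Gaussian outcome only; no random slopes; no informative priors for the
  fixed effects (the comparison target is the noninformative analysis).
* The group-level predictive-variance extension for the four-level model
  is a generative design choice of this package, documented above.
* The WAIC/PSIS-LOO likelihood is conditional on the random effects;
  leave-one-cluster-out questions need a different (marginal)
  factorization that is out of scope.
* Reported percent weight loss is treated as exchangeable across visits
  given the indicators; no serial correlation within patient beyond the
  patient intercept is modeled.
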