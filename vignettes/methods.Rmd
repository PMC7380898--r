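---
title: "Methods: matched regression-discontinuity estimation of an incentive effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched regression-discontinuity estimation of an incentive effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohctitle)
```

## The estimation problem

An online health community confers an honorary title on a subset of its
physicians at a known calendar date. The quantity of interest is the
causal effect of that award on two monthly service volumes: online
consultations and home-page views. Two features make the naive
comparison invalid:

* **Selection on merit.** Awardees are chosen partly on the very
  covariates (rating score, thank-you letters, virtual gifts,
  contribution score, articles posted) that predict future service
  volumes. We assume *selection on observables*: conditional on these
  five pre-treatment covariates, assignment is independent of the
  potential outcomes.
* **Common time shocks.** Platform-wide changes can shift every
  physician's volumes at the award date; a single-group discontinuity
  cannot separate them from the award.

The design therefore combines three standard tools. A logistic
propensity model and 1:1 nearest-neighbour matching construct a control
group comparable on observables; a sharp regression discontinuity in
calendar time estimates each group's outcome jump at the award month;
and the *differential* effect — treated jump minus matched-control
jump, a difference-in-discontinuities — removes common shocks. Matched
units are more plausibly on parallel paths, which is exactly the
assumption the differencing step needs.

## Data model

The panel is long-format, one row per physician-month, with 12 months
indexed 0–11 and the cutoff at `cutoff_index = 6` (the award falls
inside the seventh month, which is coded as the first *post* month).
Month 0 stores each variable's cumulative initial state; months 1–11
store marginal monthly changes, so `initial + cumsum(marginals)`
reconstructs the cumulative series (`marginal_changes()` performs the
forward transform). All estimation uses the flow months 1–11; the
month-0 snapshot is the pre-treatment covariate vector for the
propensity model. The covariate bound "rating score in [0, 5]" applies
to the cumulative scale: marginal rows may be (slightly) negative, as
real rating series drift both ways, and `validate_panel()` checks the
bound on the month-0 state and the reconstructed path.

## Propensity estimation and matching

`fit_propensity()` maximizes the plain logistic likelihood by
Newton–Raphson with step-halving, stopping when the score max-norm
falls below 1e-8 (at most 100 iterations). No regularization is
applied; perfect separation is detected (all treated fitted within
1e-6 of 1 and all controls within 1e-6 of 0) and reported via
`separated = TRUE` with the last iterate returned, rather than being
silently penalized. The step-halving rule guarantees a monotone
log-likelihood trace, which the tests assert. Covariates enter
untransformed by default; the heavy-tailed counts could be `log1p`-ed,
but the default follows the plain main-effects specification.

`match_nearest()` is greedy nearest-neighbour matching without
replacement, generalized to 1:N. Design choices, all made for
determinism and convention rather than optimality:

* treated units are processed in *descending* propensity score, so the
  hardest-to-match units pick first;
* exact distance ties go to the lowest control identifier;
* no caliper by default; `caliper = "auto"` in the pipeline applies the
  conventional 0.2 × SD of the logit propensity score;
* a treated unit that cannot obtain its full complement of eligible
  controls is left unmatched rather than partially matched.

Optimal (assignment-problem) matching, matching with replacement and
Mahalanobis matching are out of scope.

Balance is quantified by the absolute standardized difference with the
Cohen's-d-style denominator — the square root of the unweighted average
of the two group variances (sample variances, n−1). `balance_report()`
evaluates it for the five covariates and the propensity score itself,
before (treated vs the full pool) and after (treated vs matched
controls) matching; values below 0.1 are conventionally considered
balanced.

## RDD estimation

The running variable is the integer month index centered at the
cutoff, u = t − c, with the post indicator D = 1[u ≥ 0]: the award
month itself is the first post month, matching a mid-month award date
whose month is coded as treated. Two estimators are fitted per group ×
outcome:

* **Parametric**: least squares on
  y = α + τD + Σₖ bₖuᵏ + Σₖ cₖDuᵏ + ε, k = 1…`order` (default 1) —
  separate polynomials on each side plus a level shift. τ is the jump;
  the left/right limits at the cutoff are α and α + τ.
* **Local linear**: one weighted regression y ~ D·u with kernel weights
  K(u/h) (triangular by default, bandwidth h = 3 months), using only
  months with positive weight. Three months is a conventional
  local-linear window for an 11-point monthly series; no data-driven
  bandwidth selector is provided, deliberately. With a uniform kernel
  wide enough to cover all months, this estimator is algebraically the
  order-1 parametric fit — an identity the tests exploit.

Both are single regressions so the jump's standard error can be taken
from a cluster-robust (by physician) sandwich covariance
(`sandwich::vcovCL`): monthly observations of one physician share a
random intercept, and clustering is what keeps the 5%-level jump test
at its nominal size in the null-calibration simulations. p-values use
the two-sided normal reference with no multiplicity adjustment; the
four group × outcome cells are reported separately.

`differential_effect()` subtracts the two group jumps and combines
standard errors under independence of the group fits — conservative if
anything, since matching induces no mechanical dependence between the
two regressions. Whether to difference separate per-group fits or run
one pooled two-group regression was genuinely open; separate fits were
chosen because they keep each group's trend free and make the
group-level cells directly reportable, with the pooled variant an easy
extension.

`scan_lag()` re-fits the estimator at cutoffs shifted by 0…`max_lag`
months and selects the shift maximizing |estimate|/SE, returning the
full profile so the choice is auditable. This operationalizes the
empirical phenomenon of awards whose discontinuity surfaces only after
a delay.

## The synthetic generator

`simulate_panel()` emulates the features of the crawled-platform data
that the design relies on; magnitudes are sized loosely on the
descriptive statistics of such panels and are free parameters, not
claims:

* a latent physician "quality" factor correlating all five covariates
  and both outcome levels (month-0 states are log-normal around rating
  4.5, ~120 letters, ~600 gifts, ~80,000 contribution points, ~50
  articles);
* treatment via a weighted covariate score plus standard-logistic
  noise. The default weights (0.8, 0.004, 8e-4, 6e-6, 0.008) scale
  each raw covariate's contribution to order ~0.25 SD of the latent
  index, which produces the strong pre-matching imbalance (covariate
  ASDs well above 0.1) that gives the matching stage real work. With
  `score_threshold = NA` the top `n_treated` scores are treated
  (exact count); with a finite threshold assignment is exactly
  Bernoulli-logistic, which is what the propensity
  coefficient-recovery tests use;
* consultations: negative-binomial flows (size 10) around a mean of
  ~120/month with a −3/month drift; views: rounded log-normal flows
  (log-SD 0.3, mean parameterized so the arithmetic mean equals the
  trend) around ~160,000/month with a −4,000/month drift. The mild
  negative pre-trends mirror the declining monthly series typical of
  such platforms; the right-skewed laws mirror their log-scale
  distributions;
* additive physician random intercepts (SD 30 and 30,000) motivating
  clustered inference;
* additive jumps `jump_patients = 20` and `jump_views = 80000` per
  month from `cutoff_index + lag_months` onward for treated physicians
  only — magnitudes chosen to echo the scale of reported
  view-discontinuities (tens of thousands) versus consultation
  discontinuities (tens), not to match any particular estimate;
* defaults `n_treated = 346` (the documented cohort size of such an
  award), `n_control_pool = 3000`, `lag_months = 0`.

What it does **not** emulate: the platform's ranking algorithm,
seasonality, serial correlation beyond the random intercept,
covariate-outcome feedback, attrition, or outliers from crawling
artifacts. Green tests therefore certify the estimators' statistical
properties under the assumed model, not the substantive findings on
any real platform.

## Numerical choices and degenerate inputs

* Logistic Newton steps solve the observed-information system; a tiny
  diagonal jitter (1e-10 × max diagonal) is added only on numerical
  singularity.
* Noiseless RDD fits yield zero residual variance; the perfect-fit
  warning from the sandwich bread is muffled, and the resulting zero
  SEs simply produce degenerate z-values (the estimate itself is exact).
* Local fits drop zero-weight months; errors report the minimal
  feasible bandwidth. Parametric fits demand `order + 1` distinct
  months per side and name the deficient side.
* Missing months are permitted — fits use available months, reporting
  `n_obs` — but `validate_panel()` flags unbalanced panels before the
  pipeline runs.
* Propensity predictions are clamped to the open unit interval at
  machine precision so downstream logits stay finite.

## Problem sizes in the test-suite simulations

Monte-Carlo checks use sizes chosen to make their statistical
assertions sharp while keeping the suite quick to run routinely:
differential-jump recovery at the full study scale (346 treated, 3000
pool) over 200 replicate seeds; null calibration with 100 physicians
per group over 500 seeds (the exact binomial 95% band around 0.05 at
500 draws is [3.2%, 6.8%]); balance improvement over 50 seeds; lag
recovery over 200 seeds at 346 treated. Coefficient recovery uses
n = 5000 physicians, where 3-standard-error bands are tight enough to
detect scale errors in any single weight.

## Known limitations

* Greedy matching is order-dependent by construction; it is
  deterministic here but not distance-optimal.
* The lag scan dates a single discontinuity; it does not model gradual
  ramp-ups or multiple breaks.
* With 11 monthly points, polynomial orders above 2 are fragile; the
  default order 1 is deliberate.
* The independence assumption in the differential SE ignores any
  dependence induced by estimated propensity scores; no
  matching-uncertainty correction is attempted.
* Fuzzy designs, covariate-adjusted RDD, formal bandwidth selection and
  placebo-cutoff falsification batteries are out of scope.
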