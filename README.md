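# ohctitle

Causal analysis of an incentive award — an honorary title conferred on
selected physicians of an online health community (OHC) at a known date —
on the physicians' monthly service volumes: online consultations and
home-page views.

Platforms hand out honorary titles ("Annual Good Doctor" style awards)
hoping to stimulate physicians' web-based involvement, but awardees are
selected on merit, so a raw treated/untreated comparison confounds the
award with pre-existing quality. `ohctitle` implements the study design
that addresses this:

1. **Propensity-score matching (PSM).** The probability of receiving the
   title is modelled logistically from five pre-treatment covariates
   measured at the panel's initial month — rating score, thank-you
   letters, virtual gifts, contribution score and articles posted:

   logit P(D=1 | x) = β₀ + β₁·PRS + β₂·Thank + β₃·Gift + β₄·Contr + β₅·Article.

   Each treated physician is paired with its nearest untreated neighbour
   by propensity score (greedy, without replacement, optional caliper),
   and balance is checked with the absolute standardized difference
   ASD = |x̄ₜ − x̄꜀| / √((s²ₜ + s²꜀)/2).

2. **Sharp regression discontinuity (RDD) at the award month.** With the
   month index t as running variable and cutoff c (the award month is the
   first post month), each group's outcome jump τ = ŷ⁺ − ŷ⁻ is estimated
   two ways: a global polynomial with a post-cutoff indicator,
   y = α + τ·1[t ≥ c] + Σₖ bₖ(t−c)ᵏ + Σₖ cₖ·1[t ≥ c](t−c)ᵏ + ε,
   and a kernel-weighted local-linear fit inside a bandwidth around the
   cutoff. Standard errors are cluster-robust by physician (repeated
   monthly observations are correlated within physician).

3. **Differential treatment effect.** The difference-in-discontinuities
   τ_treated − τ_control nets out platform-wide shifts at the award date;
   a lag scan re-fits the RDD at shifted cutoffs to date effects that
   surface with a delay.

Because such OHC panels are typically web-crawled and undeposited, the
package ships a first-class synthetic generator, `simulate_panel()`,
reproducing the design's statistical structure (selection on observables,
right-skewed count outcomes, physician random effects, pre-trends, lagged
jumps) so the entire pipeline is testable end to end.

## Worked example

```r
library(ohctitle)

cfg <- synth_config(n_treated = 120, n_control_pool = 900, seed = 7)
rep <- run_pipeline(pipeline_config(synth = cfg, max_lag = 2, verbose = FALSE))
print(rep)
```

```
=== Honorary-title service-volume analysis ===
panel: 120 treated, 900 pool controls; cutoff month 6
matched controls: 120 (unmatched treated: 0)
balance: mean ASD 0.717 before -> 0.086 after

RDD jump estimates (cluster-robust SEs):
  outcome   group     method    estimate   std_error n_obs  p_value
 patients treated parametric     7.57071     5.96897  1320 2.05e-01
 patients treated      local    14.80920    10.61980   600 1.63e-01
 patients control parametric     3.83746     5.48228  1320 4.84e-01
 patients control      local    -3.56750     9.43887   600 7.05e-01
    views treated parametric 78075.30000  8625.97000  1320 1.41e-19
    views treated      local 71568.50000 16311.70000   600 1.15e-05
    views control parametric -2404.36000  6059.39000  1320 6.92e-01
    views control      local -7512.53000 12540.00000   600 5.49e-01

Differential treatment effects (treated - control jump):
  patients  parametric       3.73325  (SE 8.10456, p = 0.645)
  patients  local            18.3767  (SE 14.2082, p = 0.196)
  views     parametric       80479.7  (SE 10541.5, p = 2.27e-14)
  views     local            79081.1  (SE 20574.8, p = 0.000121)
```

Reading the output: matching collapses the covariate imbalance (mean ASD
0.72 → 0.09). The generating process gave treated physicians an 80,000
views-per-month jump at the cutoff and a 20-consultation jump; the
differential view effect recovers ≈ 80,000 and is overwhelmingly
significant, while the consultation effect — small relative to its noise,
exactly as in real OHC data — is not distinguishable from zero. Untreated
physicians show no discontinuity.

The stage functions are usable on their own: `simulate_panel()`,
`fit_propensity()` (+ `summary`, `predict`), `match_nearest()`,
`balance_report()`, `fit_rdd()` (+ `summary`, `predict`, `plot`),
`differential_effect()`, `scan_lag()`, `validate_panel()`, and CSV
readers/writers for the long-format panel. A thin command-line wrapper
with `simulate` / `validate` / `run` verbs is in `inst/cli/ohctitle.R`.

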