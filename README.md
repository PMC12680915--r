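# widowltc

Losing a spouse usually means losing one's main informal caregiver, and for
the oldest old it can tip the balance from aging-in-place to a nursing
home. `widowltc` estimates the **dynamic causal effect of spousal
bereavement on entitlement to institutional long-term care (LTC)** in a
monthly registry-style cohort of community-dwelling adults aged 75+ who
all lose their partner during a 24-month window. It is written for health
economists and epidemiologists who work with administrative panels in
which treatment timing is staggered, the outcome is an absorbing state,
and follow-up is cut short by death.

## What it implements

* **Staggered event-study estimation.** Group-time average treatment
  effects ATT(*g*,*t*) for each partner-loss cohort *g* and month *t*,
  using strictly **not-yet-treated** individuals as controls (never-widowed
  controls are systematically healthier and are excluded by design) and a
  **universal base period** *g*−1, so the effect at event time *k* = −1 is
  identically zero. Each cell is estimated **doubly robustly**: a logistic
  propensity model and an outcome regression on baseline covariates (age
  band, sex, SES, children alive, home-care use), combined so the estimate
  is consistent if either model is right. Cohort effects aggregate to an
  event-study curve γ<sub>k</sub> with weights proportional to treated
  cohort sizes.
* **Multiplier-bootstrap inference.** Per-individual influence
  contributions perturbed by Rademacher/Mammen weights; IQR-based standard
  errors and sup-t **simultaneous confidence bands**.
* **Selective-mortality correction.** Entitled individuals die faster, so
  survivor pools at long lags are depleted of the entitled and lag
  estimates drift downward. The closed-form bias

  bias(y, S<sup>L</sup>, S<sup>N</sup>) = y(1−y)(S<sup>L</sup>−S<sup>N</sup>) / (y S<sup>N</sup> + (1−y) S<sup>L</sup>)

  — with *y* the observed entitled fraction among treated survivors and
  S<sup>L</sup>, S<sup>N</sup> the survivor fractions of those entitled /
  not entitled one month before partner loss — is estimated from the panel
  and subtracted from each lag (`correct_curve()`).
* **A calibrated synthetic cohort generator.** The real registry data are
  restricted-access, so the package ships a generator whose defaults
  reproduce the study marginals (6.9% entitled before partner loss, 5.2%
  after, 6.6% dying in-window, 60% psycho-geriatric entitlements, printed
  covariate marginals) via a documented root-finding calibration, with a
  configurable true effect profile (default: a 1.5-percentage-point peak 3
  months after widowhood, gone by 10 months) realised as an exact
  timing-shift so every pipeline stage can be validated by parameter
  recovery.

## Worked example

```r
library(widowltc)

cfg <- generator_config(n_individuals = 20000, seed = 7)  # calibrated defaults
cfg
#> <ltc_config>
#>   n = 20000 persons, window = 24 months, seed = 7
#>   baseline hazard b = 0.00096, calendar trend d = 0.9721
#>   death hazards: entitled 0.0195, not entitled 0.0047 per month
#>   effect profile: peak 1.50 pp at k = 3, zero at k = 10

cohort <- simulate_cohort(cfg)
res <- event_study_pipeline(cohort,
                            settings = estimator_settings(bootstrap_reps = 199,
                                                          seed = 7))
curve <- res$curve      # mortality-corrected event-study curve
curve[curve$k %in% c(-3, -1, 0, 3, 6, 10),
      c("k", "theta", "se", "ci_lo", "ci_hi")]
#>   k  theta    se  ci_lo ci_hi
#>  -3  0.205 0.078  0.053 0.357
#>  -1  0.000 0.000  0.000 0.000
#>   0  0.426 0.071  0.287 0.564
#>   3  1.472 0.180  1.120 1.824
#>   6  0.672 0.252  0.178 1.166
#>  10 -0.177 0.330 -0.823 0.469
```

`theta` is the effect of widowhood on the probability of holding an
institutional-LTC entitlement, in **percentage points**, *k* months after
(or, for negative *k*, before) partner loss, relative to the month just
before loss. Here the estimated effect climbs to about 1.5 points three
months after widowhood — recovering the configured truth — and is
indistinguishable from zero again by ten months; the small positive
lead at *k* = −3 is sampling noise (no anticipation was configured). The
uncorrected curve is in `res$uncorrected`; comparing the two shows the
mortality bias accumulating with time since loss. `plot(curve)` draws the
curve with pointwise and simultaneous bands, and

```r
excess_entitlement_months(curve, annual_widowed = 24500, share_at_home = 0.107)
#> [1] 438.9
```

turns the area under the lag curve into additional entitlement-months per
year for a stock of newly widowed individuals still living at home.

Subgroup analyses (`stratified_run(cohort, "homecare_self")`, or `"age"`,
`"sex"`, `"ses"`, `"children"`, `"daughter"`, `"homecare_partner"`) rerun
the full pipeline within each stratum. `run_analysis()` orchestrates
everything from a YAML/list config and writes curves, attrition inputs,
mortality summaries and a reproducibility manifest as CSV/JSON
("figures as data"); a thin CLI over the same functions lives at
`inst/cli/widowltc.R` with `simulate`, `build-panel`, `estimate` and
`report` subcommands.

See the methods vignette (`vignettes/bereavement-ltc-methods.Rmd`) for the
model, the generator's assumptions and the design decisions.

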