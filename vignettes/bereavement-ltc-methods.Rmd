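---
title: "Estimating the effect of spousal bereavement on institutional long-term care entitlement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the effect of spousal bereavement on institutional long-term care entitlement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When an older person loses their spouse they lose, in most cases, their main
informal caregiver. `widowltc` estimates how strongly, and for how long,
widowhood raises the probability of being granted an *entitlement* to
institutional long-term care (LTC) — the Dutch-style, nationally assessed
approval for round-the-clock nursing-home care — in a monthly registry-style
cohort of community-dwelling adults aged 75+ who all lose their partner at
some point in a 24-month observation window.

Three features of such data shape the whole design:

* **Staggered treatment.** Partner deaths are spread roughly uniformly over
  the window. Every individual is eventually treated; never-widowed couples
  are deliberately *not* used as controls, because having a living partner
  is itself protective and such controls would bias the comparison. The
  only valid comparison group is the *not-yet-treated*: people whose partner
  dies later.
* **An absorbing binary outcome.** Once granted, an entitlement stays.
  The outcome at month `s` is "entitled by `s`", so event-time effects are
  accumulated effects of monthly inflows.
* **Selective attrition by death.** In a cohort defined by surviving one's
  partner, own mortality only occurs after partner loss, and entitled
  individuals die at a substantially higher monthly rate than non-entitled
  ones. Survivor pools at longer lags are therefore depleted of the
  entitled, which mechanically drags long-lag effect estimates downward.

## The estimator

For the cohort losing a partner in month $g$ and an outcome month $t$, the
group-time average treatment effect on the treated is estimated as

$$\widehat{ATT}(g,t) \;=\;
\Big[\bar Y^{\,obs}_{g\text{-cohort}}(t) - \bar Y_{g\text{-cohort}}(g-1)\Big]
\;-\;
\widehat{E}\Big[Y(t) - Y(g-1)\,\Big|\,\text{not yet treated at } \max(t, g-1)\Big],$$

with a *universal base period* $g-1$: every contrast, for leads and lags
alike, is measured against the month before partner loss, so the effect at
event time $k=-1$ is identically zero by construction and pre-loss
anticipation shows up as non-zero leads.

The comparison-group term is estimated **doubly robustly**: a logistic
propensity model for membership of the treated cohort (fit by iteratively
reweighted least squares on the baseline covariates: age band, sex,
neighbourhood socioeconomic status, number of children alive, home-care
use), an outcome regression of the comparison group's long difference on
the same covariates, and the standard combination — the reweighted
comparison residual plus the outcome-regression prediction averaged over
the treated. `ipw` and `reg` variants are available; all three coincide
when covariates carry no information.

Two estimability boundaries are intrinsic: the cohort treated in the first
month has no base period, and the last cohort has no not-yet-treated
comparison, so neither contributes cells. Calendar-time effects common to
all individuals cancel within each $(g,t)$ contrast and are not estimated
as parameters.

**Why per-period available-case means on the treated side?** Deaths thin
the treated cohort at post-loss outcome months, while the comparison group
(still pre-loss at both of its months) is always fully observed. We use the
baseline mean over the *whole* treated cohort (complete by construction)
and the follow-up mean over the *survivors*. The alternative — differencing
within the surviving individuals only — quietly removes most of the
attrition bias for some mortality structures and leaves an unknown
remainder; the available-case contrast instead leaves the *full*
level-composition bias in the lags, and that bias has a known closed form
(below), so it can be removed exactly in a second, transparent step. This
two-step division of labour is deliberate: the estimator module does not
try to fix mortality selection.

Event-study aggregation weights each estimable $ATT(g, g+k)$ by the number
of treated individuals in cohort $g$. Inference uses the **multiplier
bootstrap** on per-individual influence contributions: each draw perturbs
individuals (never single person-months) with i.i.d. Rademacher (or
Mammen) weights, standard errors are the bootstrap interquartile range
rescaled by the normal quantile spread (robust to heavy-tailed draws), and
the simultaneous band uses the sup-t statistic across event times. The
influence functions treat the fitted propensity and outcome regression as
known; by the orthogonality of the doubly robust moment this neglects only
higher-order terms when either working model is correct, and both are
correctly specified under the generator below. Aggregation weights are
likewise treated as fixed.

## The mortality correction

Classify treated individuals by entitlement status one month before
partner loss: class $L$ (entitled) versus $N$ (not). With survivor
fractions $S_k^L$, $S_k^N$ at $k$ months after loss and observed entitled
fraction $y$ among survivors, the expected lag estimate equals the true
effect plus

$$\text{bias}(y, S_k^L, S_k^N) \;=\;
\frac{y\,(1-y)\,\big(S_k^L - S_k^N\big)}{y\,S_k^N + (1-y)\,S_k^L},$$

which is negative whenever the entitled die faster and grows in magnitude
with $k$. The package validates this formula against an independent
two-group thinning oracle: starting from any pre-attrition entitled
fraction $p$ and thinning the two classes binomially, the observed
fraction $\tilde y$ satisfies $\tilde y - p =
\text{bias}(\tilde y, S^L, S^N)$ *identically*. `correct_curve()`
subtracts the estimated bias from each lag; leads are untouched.

Estimation choices for the ingredients: survivor fractions are pooled over
treatment cohorts with count weights (averaging survival over calendar
seasons), $y_k$ is measured among survivors at $k$ (the reading consistent
with the oracle identity), and only cohorts for which month $g+k$ lies
inside the window contribute at lag $k$. The classification is exact at
the individual level because pre-loss entitlements are never censored
(deaths only occur after loss). Uncertainty in the estimated bias is *not*
propagated — the correction is a plug-in shift, so corrected and
uncorrected curves carry the same standard errors. The correction is
approximate to the extent that class-$N$ members who become entitled after
the classification month acquire the higher mortality (class switching);
tests show the residual error is well inside Monte-Carlo noise at the
default configuration.

## The synthetic cohort generator

The real registry data are restricted-access, so the package ships a
generator whose *defaults are the study conditions*:

* **Covariates** are drawn from the packaged baseline marginals table (sex,
  five age bands, home-care use, children alive, neighbourhood SES,
  plus a partner home-care flag at 68% and daughter presence at
  $1 - 0.5^{\#\text{children}}$).
* **Partner-death months** are uniform over the 24 months.
* **Baseline entitlement hazards** are piecewise-constant by covariate
  cell: relative risks across age bands (1 to 12) and home-care use (7),
  a two-point unobserved frailty multiplier (20% of individuals at 3 times
  the hazard), and a mild multiplicative calendar decline. Frailty and the
  calendar trend are independent of the partner-death month, so parallel
  trends hold exactly, conditionally and unconditionally; together with
  depletion of the susceptible pool they reproduce the observed asymmetry
  between pre-loss and post-loss entitlement rates.
* **Calibration** of the three free scalars — the hazard scale $b$, the
  monthly calendar factor $d$, and the non-entitled death hazard $h_N$
  (entitled hazard fixed at $\tfrac{25}{6} h_N$, preserving the roughly
  2.5% vs 0.6% contrast) — is a documented root-finding step
  (`calibrate_generator()`): Gauss–Seidel over three nested `uniroot`
  solves matching closed-form cohort expectations to the printed study
  marginals of 6.9% entitled before loss, 5.2% at or after, 6.6% dying
  in-window. The closed-form engine (`cohort_expectations()`) enumerates
  hazard cells, loss months and event times exactly, and doubles as an
  independent oracle for the simulator in the test suite. Calibrated
  defaults land near $b \approx 9.4\times10^{-4}$, $d \approx 0.975$,
  $h_N \approx 0.0044$.
* **The treatment effect is a timing shift.** A configured profile
  $\Delta(k)$ (default: rising to 1.5 percentage points at $k=3$ and
  decaying linearly to zero at $k=10$) is realised by *advancing*
  counterfactual entitlements that would occur $j \in (3, 10]$ months
  after loss into months $g..g+3$, with cohort-specific pull
  probabilities $\pi_j(g) = \frac{\Delta(j-1)-\Delta(j)}{P_j(g)}$. This
  telescopes so that *every cohort's* implied event-study curve equals
  $\Delta(k)$ exactly — hence any aggregation over any subset of cohorts
  is unbiased for the configured truth — and it automatically produces
  the transient hazard surplus followed by a deficit ("controls catch
  up") that an absorbing outcome with a vanishing long-run effect
  requires, without ever generating a negative hazard. Any non-negative
  profile rising to a single peak and ending at zero is admissible;
  infeasible profiles (a pull probability above one inside the estimable
  window) are rejected at configuration time with the offending event
  time named. For the latest cohorts, decay months falling beyond the
  window (never estimable) may silently cap at probability one.
* **Mortality** occurs only in months after partner loss, with the hazard
  switching from $h_N$ to $h_E$ the month after entitlement; a death at or
  before the entitlement month voids the entitlement (it is never
  observed). Entitlement types are psycho-geriatric with probability 0.6,
  somatic otherwise.
* An optional **anticipation dip** postpones a configurable fraction of
  counterfactual entitlements from the four months before loss to just
  after it (off by default), for studying pre-trend violations.

Seeding: one master seed; every person's history is a deterministic
function of their own row of draws, so subsetting a generated cohort
preserves histories. Regenerating with a different cohort size does not
reproduce the first rows.

**What the generator does *not* emulate.** Couples' joint health dynamics
(the partner appears only through a baseline home-care flag), time-varying
covariates, seasonality, regional supply constraints, application-to-
entitlement processing delays as a separate process, and cause-of-death
structure. Passing the parameter-recovery tests therefore shows that the
estimator and correction do what they claim under the stated statistical
structure — staggered adoption, absorbing outcome, selective attrition —
not that the pipeline is robust to every feature of real registry data.

## Numerical choices and degenerate inputs

* Propensity scores above 0.999 anywhere in a cell's sample raise an
  error naming the cell (small synthetic samples should fail loudly, not
  be silently trimmed). In the batch sweep over all cells the same
  condition marks that one cell not-estimable, with the reason logged and
  a warning — a rare covariate level concentrated by chance in one thin
  cell should cost that cell, not the run.
* Cells at the base period, without treated observations, or without
  not-yet-treated comparisons are recorded as *not estimable* with a
  reason, and excluded from aggregation; the log of skipped cells rides
  along in the `att_gt_all()` result so silent sparsity cannot corrupt an
  aggregate.
* The bias formula's denominator $y S_N + (1-y) S_L$ must be positive;
  zero raises a domain error. Event times with an empty survivor class
  yield `NA` inputs and are left uncorrected with a warning.
* A person entitled in the same month their partner dies counts at
  $k = 0$; a person dying in month $m$ contributes observations through
  $m-1$ only (the death month itself yields no row).
* Bootstrap draws are taken in blocks so the $B \times n$ weight matrix
  never exceeds a few hundred megabytes.

## Problem sizes used in the checks

The packaged checks simulate 48,997 individuals for the calibration
marginals (matching the printed cohort total; the companion text also
prints 48,996 — the one-person discrepancy is noted, not resolved, and the
larger figure is used), 50,000 for full-pipeline parameter recovery with
999 bootstrap draws, 200 replications of 2,500 individuals with 199 draws
each for the null-coverage study, and cohorts of 1,500–60,000 for the unit
and property tests. These sizes were chosen so each check has the
precision its tolerance needs.

## Known limitations

* Standard errors are not adjusted for the estimated attrition inputs or
  for the estimated aggregation weights; both are treated as known.
* The influence functions omit the nuisance-estimation terms of the
  propensity and outcome models (exactly zero to first order only under
  correct specification of at least one of them).
* The correction assumes classification at one month before loss;
  class switching afterwards makes it slightly conservative upward at very
  long lags.
* With strongly cohort-heterogeneous effect profiles the aggregated curve
  is a treated-count-weighted mixture across cohorts, which is what the
  estimator reports but need not equal any single cohort's profile.
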