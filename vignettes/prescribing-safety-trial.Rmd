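---
title: "Simulating and analysing cluster-randomised prescribing-safety feedback trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing cluster-randomised prescribing-safety feedback trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxsafetrial)
```

## The problem

Feedback of prescribing-safety data to general practices is a cheap,
system-wide intervention: each quarter a practice is shown its rate of
high-risk prescribing against a benchmark. Evaluating such an intervention
requires a *cluster randomised* design -- the feedback acts on the practice,
and patients within a practice are correlated -- and the analysis must respect
that clustering. `rxsafetrial` packages every stage of such a trial as
testable code: the outcome definitions, a synthetic dispensing-data generator
with realistic clustering, the stratified randomisation, the power
calculation, and the two estimation procedures (a random-intercept logistic
endpoint model and a segmented GEE over the quarterly panel).

## Outcomes: six indicators and a composite

Measurement is a repeated quarterly cross-section at patient level. At the end
of each quarter, a patient is *at risk* if they fall into at least one of six
indicator denominators, and a *numerator* case if they received the
corresponding high-risk prescription in that quarter:

| | Denominator | Numerator |
|---|---|---|
| S1 | aged 75+ | oral antipsychotic |
| S2 | aged 65+, on diuretic + ACEI/ARB | oral NSAID (the "triple whammy") |
| S3 | aged 75+ | oral NSAID without gastroprotection |
| S4 | aged 65+, on aspirin/clopidogrel | oral NSAID without gastroprotection |
| S5 | on oral anticoagulant | oral NSAID without gastroprotection |
| S6 | on oral anticoagulant | aspirin/clopidogrel without gastroprotection |

The primary outcome is the patient-level composite: membership of any
denominator, receipt of any corresponding numerator prescription. Note that
gastroprotection removes numerators for S3--S6 but *not* for S2.

Two operationalisations are deliberate and configurable rather than inferred
from data we do not have: "currently treated with" means at least one
dispensed event of the class within the measured quarter (a single-quarter
window matches the cross-sectional design), and age is completed years at the
quarter end, advancing one year every four quarters. Gastroprotection counts
if dispensed anywhere in the same quarter as the hazard drug; whether the
source analyses required same-form co-prescription is unknowable from the
published material, and the same-quarter rule is the weaker, documented
choice. S1 is a proxy for antipsychotic use in dementia; the data model
carries no dementia flag, mirroring the dispensing data it emulates.

```{r}
classify_patient_quarter(80, c("ORAL_NSAID", "GASTROPROTECTION"))[c("S3_den", "S3_num")]
```

## The synthetic cohort generator

No dispensing data can be shipped, so the generator is a first-class module
that emulates the statistical structure the analysis assumes:

* **Clustering.** Each practice carries a random intercept
  $u_j \sim N(0, \sigma_u^2)$ on the log-odds scale. $\sigma_u$ is solved from
  a target intraclass correlation on the *observed binary* scale (the scale on
  which an ICC computed from a routine dataset lives): with
  $p(u) = \mathrm{expit}(\alpha + u)$, the ANOVA ICC is
  $\mathrm{Var}_u\,p(u) / \bar p(1-\bar p)$, and `sigma_from_icc()` inverts
  this mapping by Gauss--Hermite quadrature and root finding. The default
  target, ICC = 0.0126 at prevalence 6.1%, gives $\sigma_u \approx 0.457$.
* **Trend and effects.** The composite hazard for patient $i$ in practice $j$
  at time $t$ (years, centred at the baseline quarter) fires with probability
  $\mathrm{expit}(\alpha_0 + u_j + \mathrm{off}_i + \gamma t +
  \mathbf{1}[t>0](\delta_a + \theta_a t))$: a shared declining secular trend
  ($e^\gamma = 0.92$/year by default), and per-arm step ($\delta_a$) and
  slope-change ($\theta_a$) terms that switch on after the baseline quarter.
  Step sizes are configured in the reporting convention of the change-point
  model -- the implied odds ratio between the first post-intervention quarter
  and baseline, $\exp(\delta_a + \theta_a/4)$ -- and converted internally.
* **Timeline.** Eleven quarters indexed $-5..+5$; baseline is quarter 0, the
  intervention starts after it, and quarter $+5$ ($t = 1.25$ years) is the
  15-month endpoint.
* **Indicator mix.** Patients carry an age group (8% under 65 / 31% 65--74 /
  61% 75+) and chronic risk classes (diuretic+ACEI/ARB 32% of over-65s,
  antiplatelet 55%, anticoagulant 3.5%; under-65s enter only via
  anticoagulation). A fired composite event is realised as one concrete
  prescription chosen among the patient's eligible channels (unprotected
  NSAID, antipsychotic, gastro-protected NSAID for triple-whammy patients,
  aspirin for anticoagulated patients) with configured weights. Patient-level
  log-odds offsets by risk class (+0.65 diuretic+ACEI, -0.65 antiplatelet,
  -0.25 anticoagulant) reproduce the fact that per-indicator rates differ
  systematically -- a uniform event probability cannot make the triple-whammy
  rate (~7.8%) exceed the composite (~6.1%) while antiplatelet-only patients
  sit near 2.7%. The conditional intercept $\alpha_0$ is re-solved numerically
  so the marginal baseline prevalence stays at the configured 6.1% whatever
  offsets and $\sigma_u$ are in force. These defaults were fixed once, from an
  expected-value calculation over the finite patient-type distribution
  targeting the pooled baseline rates of the emulated trial, and are not
  data-fitted.
* **Churn.** Chronic classes persist with 95% quarterly retention and are
  re-acquired at the stationary rate, so denominators are stable cross-sections
  with realistic turnover. Hazard events are drawn fresh each quarter.
* **Bookkeeping constraints.** Anticoagulant and chronic antiplatelet classes
  are mutually exclusive (otherwise their co-occurrence would mint S6
  numerators outside the composite-event model and dilute injected effects);
  background gastroprotection is suppressed in quarters with an active
  unprotected hazard, and background protected NSAIDs are emitted only
  outside the S2 denominator, for the same reason. Inert `OTHER` events are
  sprinkled in to exercise the engine's invariance to them.

What the generator does *not* emulate: seasonality, practice list growth or
closure, death and deregistration, dose/duration information, real drug
coding, or indication-aware exceptions. Passing tests therefore demonstrate
that the estimators recover known truth under the assumed clustered logistic
structure -- not that they are robust to every failure mode of real dispensing
data. A shared pre-intervention trend is assumed (the emulated trial reports
a single pooled pre-trend); per-arm pre-trends can be configured.

## Design: stratification, randomisation, power

Practices are ranked by composite prevalence over the year before baseline
and cut into thirds (remainders to the lower thirds, ties by practice id).
Randomisation is stratified by health board x baseline third: within each of
the nine strata practices are dealt to three *groups* in randomly ordered
blocks, stratum remainders going to the groups with the smallest running
totals, which guarantees global group sizes differ by at most one (262
practices always split 88/87/87). A second, independently seeded permutation
maps groups to arms -- the blinding step. Simple (unblocked) randomisation is
available behind `method = "simple"`.

Power for comparing two proportions uses the design-effect-adjusted normal
approximation: effective sample size $km/(1 + (m-1)\rho)$ per arm and
$\mathrm{power} = \Phi\big(|p_1-p_2|\sqrt{n_\mathrm{eff}/(p_1q_1+p_2q_2)}
- z_{1-\alpha/2}\big)$. At the emulated trial's parameters (6.1% control
rate, exact 25% relative reduction, $m = 700$, $\rho = 0.0126$, 85 clusters
per arm, two-sided $\alpha = 0.025$ per comparison so that two primary
comparisons control an overall 5% level) this gives 93%:

```{r}
power_two_proportions_cluster(0.061, relative_reduction = 0.25,
                              m = 700, icc = 0.0126, k = 85, alpha = 0.025)
```

The printed "6.1% to 4.5%" in such sample-size statements is display
rounding of an exact 25% reduction (4.575%); the formula reproduces the
stated power only under the exact reduction. `simulate_power()` is the
Monte-Carlo check: beta-binomial cluster outcomes matching $(p, \rho)$,
analysed by a cluster-level t test (or a quasibinomial GLM), agree with the
closed form to within Monte-Carlo error.

## Estimation 1: random-intercept logistic endpoint model

The primary analysis compares arms on the final-quarter cross-section with a
practice-level random intercept, adjusted for the two stratification
variables (board, baseline third):
$\mathrm{logit}\,P(y_{ij}=1|u_j) = x_{ij}'\beta + u_j$. `fit_mixed_logit()`
maximises the exact marginal likelihood, integrating $u_j$ out by *adaptive*
Gauss--Hermite quadrature: each cluster's integrand is recentred at its mode
(found by a vectorised Newton iteration) and scaled by its curvature, so 15
points suffice even with 700 patients per practice (1 point is the Laplace
approximation; the tests show 1 vs 25 points move odds ratios by under 2%).
Since all adjustment covariates are practice-level, patient rows aggregate
losslessly to practice-level binomial counts, which is how the pipeline calls
it. Standard errors are model-based Wald from the numerically differentiated
observed information (a sandwich option is deliberately not the default,
matching standard multilevel reporting); $\sigma_u$ is kept in bounds by
L-BFGS-B, and when it collapses to the boundary the information is taken over
$\beta$ alone. Baseline adjustment uses the categorical thirds that entered
stratification; a continuous-baseline covariate can be passed in the formula
instead.

The implementation is verified three ways: against brute-force trapezoid
integration of the marginal likelihood on a tiny fixture (to 1e-6 and
better), against an ordinary logistic fit when $\sigma_u = 0$, and against an
independent multilevel implementation (lme4) on shared simulated data.

## Estimation 2: segmented GEE change-point model

Trends are analysed marginally on the practice-quarter panel: a binomial GEE
(logit link, denominator-weighted proportions) with linear predictor
$\alpha + \gamma t + \sum_a \mathbf{1}[\mathrm{arm}=a]\,\mathrm{post}_t
(\delta_a + \theta_a t) + \text{board} + \text{third}$ -- a common
pre-intervention trend, and an immediate level shift plus a trend change for
*each* arm at the change point (the first feedback quarter, directly after
baseline). The estimating equations are solved by IRLS with moment updates of
the working correlation; the default is unstructured over the 11 quarters (55
free parameters), with an automatic, warned fallback to exchangeable below 30
practices. Variances are cluster-robust sandwich
($B^{-1} M B^{-1}$, clusters = practices). Convergence requires
$\max|\Delta\beta| < 10^{-8}$ within 100 iterations, and the score norm at
the solution is checked.

Reported odds ratios follow the segmented-regression convention: the
pre-trend $e^\gamma$ and slope changes $e^{\theta_a}$ are per year of
follow-up; the "immediate change in level" is the model-implied contrast
between the first post-intervention quarter and baseline net of the secular
trend, $\exp(\delta_a + \theta_a \Delta t)$ with $\Delta t = 0.25$ years,
with its variance from the full sandwich covariance of the contrast. The
choice matters only when $\theta_a \ne 0$ and is stated here because the
contrast algebra is otherwise ambiguous.

Analysis rows are practice-quarter binomial counts rather than patient rows:
with practice-level covariates the score equations are identical and the fit
is two orders of magnitude cheaper. Note one scale subtlety: the GEE is a
population-averaged model, so with $\sigma_u \approx 0.46$ its coefficients
are attenuated by roughly 0.4% relative to the cluster-conditional generator
values -- far inside the recovery tolerances used in the tests.

## Numerical choices and degenerate inputs

* Wald binomial intervals are the default (`prevalence_with_ci`), clamped to
  [0, 1], because they reproduce conventional published intervals after
  rounding; Wilson is available behind a flag.
* Quadrature: 31 points for the scalar calibration integrals, 15 for
  estimation; nodes by Golub--Welsch eigendecomposition.
* The unstructured working correlation estimate is projected to the nearest
  positive-definite correlation (eigenvalue clipping) when a replicate makes
  it singular.
* Ties in `assign_thirds` break by practice id; stratum remainders in the
  randomiser go to the smallest running groups with random tie-breaks.
* Degenerate inputs error early and loudly: empty cohorts, duplicate patient
  ids within a practice-quarter, unknown drug classes, constant outcomes,
  single clusters, denominators of zero, allocations not covering every
  practice. Non-convergence is flagged on the fit object and warned, never
  silent; separation produces a warning.
* All randomness is seeded; derived seeds are mixed per stage *and per
  quarter*, so any subset of quarters regenerates identically and
  pre-intervention data are provably independent of the allocation.

## Problem sizes used in the tests

The test suite verifies estimator calibration at deliberately reduced scale,
chosen to keep Monte-Carlo noise well inside the assertion bands: endpoint-model
recovery uses 200 replicates of 200 practices x 150 patients (true arm OR
0.88; mean recovered OR and 95% coverage checked), change-point recovery 200
replicates of 150 practices x 200 patients x 11 quarters, and the null size
of the step/slope tests 1000 replicates of 200 practices. Generator
calibration is checked on a 300-practice x 700-patient cohort (rates within
30% relative of their targets; composite within 0.5 points) and the ICC round
trip on 500 practices (within 0.004). Full trial scale (262 practices x ~700
patients) runs in a few minutes via `run_trial()` but is not exercised in the
routine suite.

## Known limitations

* The generator's per-indicator decomposition is a modelling choice
  constrained only by pooled baseline rates; arm-by-indicator interactions are
  not separately configurable (effects act on the composite hazard).
* Small-sample GEE corrections (Kauermann--Carroll, Mancl--DeRouen) and
  autoregressive working correlations are not implemented; with 30+ clusters
  the uncorrected sandwich holds its size in the null simulations.
* Random slopes, crossed random effects and Bayesian estimation are out of
  scope for the endpoint model.
* Per-arm baseline prevalence at trial scale has a cluster-driven standard
  error of ~0.3 percentage points; reports at reduced scale will show
  correspondingly larger arm-to-arm wobble.
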