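---
title: "Methods: CERT scores, hypertension models and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CERT scores, hypertension models and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certscore)
```

# The scoring system

The package implements the two Coronary Event Risk Test scores over a
seven-species plasma lipid panel measured by targeted LC-MS/MS: four
ceramides (Cer(d18:1/16:0), Cer(d18:1/18:0), Cer(d18:1/24:0),
Cer(d18:1/24:1)) and three phosphatidylcholines (PC(14:0/22:6),
PC(16:0/22:5), PC(16:0/16:0)), all on one common concentration unit.

Each score is a sum of quartile points over its components:

* **CERT1**: six components — the concentrations of Cer(d18:1/16:0),
  Cer(d18:1/18:0), Cer(d18:1/24:1), and the ratios of these three species to
  Cer(d18:1/24:0) — with point map (0, 0, 1, 2) over quartiles Q1–Q4.
  Maximum 6 × 2 = 12.
* **CERT2**: four components — Cer(d18:1/24:1)/Cer(d18:1/24:0),
  Cer(d18:1/16:0)/PC(16:0/22:5), Cer(d18:1/18:0)/PC(14:0/22:6), and the
  PC(16:0/16:0) concentration — with point map (0, 1, 2, 3). Maximum
  4 × 3 = 12, so both scores live on the same 0–12 scale.

Numerical conventions that the source score descriptions leave open, fixed
here and configurable:

* **Quantile convention.** Quartile boundaries are the 25th/50th/75th
  percentiles under linear interpolation between order statistics
  (`stats::quantile(type = 7)`, the default convention in scientific
  software). `fit_quartiles()` exposes `quantile_type`.
* **Boundary ties.** A value exactly on a cut belongs to the *lower*
  quartile: membership intervals are (−Inf, c1], (c1, c2], (c2, c3],
  (c3, Inf). With the conventional "higher quartile = higher risk" maps this
  is the conservative reading.
* **Boundary source.** Quartiles are fitted once on the whole input cohort
  (`cohort_internal`). For clinical scoring against frozen published
  cut-points, `score_cohort(boundaries = ...)` accepts an external reference
  table and records its provenance in the audit output.
* **Degenerate data.** If ties collapse one or more cuts the boundary row is
  flagged (`degenerate = TRUE`) with a warning; fewer than four finite
  values is an error.
* **Missing lipids.** Complete-case exclusion with a reported count; no
  imputation. Exclusions are carried in the `n_excluded` attribute and the
  pipeline manifest.
* **Risk categories.** The four CVD-risk bands are not numerically fixed by
  the score's textual description; the defaults here — CERT1 0–2 / 3–6 /
  7–9 / 10–12 and CERT2 0–3 / 4–6 / 7–8 / 9–12 — follow the published score
  literature and are fully configurable via the category scheme argument.

# Association models

**Outcome definitions.** *Prevalent* hypertension at baseline: current
BP-lowering treatment, or SBP ≥ 140 mmHg, or DBP ≥ 90 mmHg (SBP/DBP are
means of three readings). *New-onset* hypertension: initiation of
BP-lowering treatment during the 10-year follow-up among subjects free of
hypertension at baseline. Prevalent subjects are excluded from the
new-onset analysis set, so the two indicators are never both true for one
analysis subject.

**Prevalent (logistic).** `fit_prevalent()` fits maximum-likelihood
logistic regression and reports the OR per unit of the predictor with a
Wald 95% CI on the log scale. Adjustment sets: M1 = age + sex;
M2 = M1 + total, HDL and LDL cholesterol; M3 = M2 + BMI + current smoking +
diabetes + lipid-lowering treatment. Apparent complete separation
(non-converged fit or |log OR| > 15) is an error, never silent output.

**New-onset (Cox).** `fit_new_onset()` fits a proportional-hazards model
with *attained age* as the time axis: subjects enter the risk set at their
baseline age (left truncation) and exit at onset or censoring age. Sex is a
stratum, not a covariate; ties use the Efron approximation; M1 is not
fitted, since age is the timescale and sex the stratum — M2 and M3 contain
only the remaining covariates.

**Predictor scaling.** CERT totals enter as raw points, so estimates read
"per score point". Lipid species and ratios are standardized to SD 1 by
default, so estimates read "per SD" — the magnitude scale on which such
lipid effects are conventionally reported; `standardize = FALSE` switches
to raw units, and a log-transform can be applied upstream. Both choices are
visible in the function signatures rather than buried in the suite.

**Inference conventions.** Wald CIs and p-values for both families;
significance flagged at p < 0.05 with no multiple-testing correction,
matching the analysis style the suite reproduces. Sex-stratified refits and
a sex × predictor interaction (Wald test) are available via
`sex_analyses = TRUE`.

# Risk curves

`risk_curve()` winsorizes the predictor at the 1st/99th percentiles and
fits a loess regression of the binary outcome on it: degree 2, span 0.75,
tricube weights (the conventional defaults; none are fixed by the source
description), evaluated on 100 evenly spaced grid points with a pointwise
normal-approximation 95% band (fit ± 1.96 × SE). The curve estimates the
event probability as a function of the predictor; near the grid boundary
the local-polynomial variance grows, which the band reflects.

Winsorization uses interpolated percentiles; because re-estimating
percentiles on already-clipped data can move the limits inward by up to one
order-statistic gap, exact idempotence holds when the percentile positions
fall on order statistics or when the previous limits are passed back via
`limits` (they travel as an attribute). In general the re-applied
transformation differs by at most one tail order-statistic gap, which the
test suite asserts.

# The synthetic cohort generator

The restricted survey data cannot be redistributed, so `simulate_cohort()`
generates cohorts with the statistical structure the analyses assume,
calibrated to the published baseline table of a FINRISK-like survey
(adults 25–74, 46.2% men). What it emulates:

* **Demographics.** Age is truncated normal on [25, 74]. The underlying
  location/scale are *moment-matched* so that the truncated distribution has
  exactly the configured mean 46.7 y and SD 12.9 y — naive truncation would
  shift the mean by ~0.75 y. The same matching is applied to every bounded
  continuous covariate (BMI 26.5 (4.5) kg/m², waist 88.2 (13.1) cm,
  TG 1.4 (0.9), TC 5.6 (1.1), HDL 1.5 (0.4) mmol/L).
* **LDL.** The published table prints no LDL row although the adjustment
  models use it; the default (3.5 (1.0) mmol/L) is a realistic value
  consistent with the TC/HDL/TG marginals by Friedewald-style arithmetic.
* **CRP.** Mean 2.4, SD 4.9 mg/dL — an SD twice the mean is incompatible
  with a normal restricted to positive values, so CRP is log-normal with
  moment-matched parameters.
* **Lipids.** Multivariate log-normal (concentrations are positive and
  right-skewed). Typical plasma locations are taken from the
  ceramide-biomarker literature; correlations default to 0.4 within lipid
  class and 0.2 across classes and are fully overridable. The published
  analysis gives neither distributions nor correlations.
* **Prevalent hypertension.** Drawn from a logistic model whose linear
  predictor combines configured per-covariate log-odds with a per-CERT2-point
  effect (default log 1.36, the published unadjusted association). The
  intercept (−11.60 under the default covariates) is calibrated so ~11.3%
  of subjects are prevalent, the published proportion 875/7722.
* **Blood pressure.** SBP/DBP and treatment are drawn *jointly with*
  prevalent status so the threshold rule and the simulated indicator agree
  by construction: non-prevalent subjects are untreated with SBP < 140 and
  DBP < 90 (truncated normals around 129/77 mmHg); prevalent subjects are
  treated with probability 793/875 (any BP) or untreated with SBP ≥ 140
  (truncated normals around 162/84 mmHg); DBP is always at least 5 mmHg
  below SBP.
* **New-onset hypertension.** A Weibull proportional-hazards model on the
  attained-age scale (shape 4.6 — incidence rising steeply with age; scale
  126 y calibrated so ~18% of the hypertension-free develop hypertension in
  10 years, the published 1225/6846), with a per-CERT2-point log-HR (default
  log 1.16). Onset ages are drawn by closed-form inversion of the
  conditional cumulative hazard given event-free survival to baseline age.
  Death is independent exponential censoring (rate 0.0097/y, ≈ 9.2% in 10
  years); administrative censoring at baseline age + 10 y. Competing-risk
  modelling is deliberately omitted.
* **Determinism.** One master seed; sub-streams are derived deterministically
  per variable block, so identical configurations give byte-identical
  cohorts.

What it does **not** emulate, hence what passing tests do and do not show:
lipids are simulated independently of age, sex and adiposity, so adjusted
and unadjusted effects coincide in the generator while they differ in real
cohorts (the published CERT attenuation under M3 cannot arise here); there
are no survey weights, regional strata, assay batch effects, registry
linkage artefacts, or informative censoring. Tests on this generator
validate the *estimators and plumbing* — quartile logic, left truncation,
stratification, CI construction — not the epidemiology of any real
population. A small internal inconsistency of the published counts (both
study groups reported as 7722 while the new-onset panel sums to 6846) is
left unresolved: the generator simply treats the new-onset set as the
prevalent-free subset.

The two calibrated constants (prevalent intercept, Weibull scale) were
solved numerically against the target proportions under the default
marginals and then frozen in `default_finrisk_config()`.

# Verification strategy and problem sizes

The test suite checks each layer against an independent oracle: quartile
cuts against a brute-force interpolation on the sorted list; the
one-binary-predictor logistic OR against the 2×2 cross-product ratio (MLE
identity, tolerance 1e-6); the small-sample Cox log-HR against grid-search
maximization of the hand-written partial likelihood (tolerance 1e-3); loess
curves against flat, step and linear truths. Parameter recovery uses 50
simulations of n = 20 000 per model family and requires ≥ 90% coverage of
the generative per-point effect by the 95% Wald CIs; marginal calibration
uses n = 6000 within 4 standard errors; scoring invariants (range 0–12,
monotonicity under fixed boundaries, quartile occupancy n/4 ± 1 on tie-free
data, permutation invariance) run over seeded cohorts of n = 800–1000.
These sizes keep every check well-powered while the whole suite completes
in minutes.

# Known limitations

* Generator realism is limited as described above; it is a testbed, not a
  population model.
* Quartile boundaries estimated cohort-internally are sample statistics;
  scoring a new subject requires either the original cohort or frozen
  external boundaries.
* The Cox implementation assumes proportional hazards on the age scale and
  non-informative censoring by death; no competing-risks or time-varying
  covariate support.
* Loess bands are pointwise normal approximations, not simultaneous bands,
  and widen sharply at the winsorized range boundaries.
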