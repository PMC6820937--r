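---
title: "Methods: glycemia-aware GFR approximation and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycemia-aware GFR approximation and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycogfr)
```

## Scientific setting

Measured GFR (iothalamate clearance, divided by Du Bois body surface
area and indexed to 1.73 m²; "aGFR") is the reference standard for
kidney function, but it is impractical clinically, so creatinine-based
estimates (CKD-EPI, MDRD) stand in for it. In adults with type 2
diabetes these estimates underestimate aGFR, increasingly so at high
aGFR, partly because hyperglycemia raises filtration while leaving
serum creatinine (SCR) nearly uninformative about that rise. This
package implements a family of *approximating equations* that add
fasting plasma glucose (FPG, mg/dL) and HbA1c (%) to age, sex and SCR,
together with the machinery to derive such equations from a
longitudinal cohort and to quantify what they buy.

## The longitudinal regression model

All derivation regressions are marginal linear models with a
first-order autoregressive residual within subject:

$$y_{ij} = x_{ij}'\beta + e_{ij}, \qquad
  \operatorname{corr}(e_{ij}, e_{ik}) = \rho^{|j-k|},$$

where $j$ orders subject $i$'s examinations. Outcomes are the natural
log of aGFR, the reciprocal of SCR (dL/mg), or the difference
aGFR − eGFR. `fit_lmm_ar1()` evaluates the AR(1) likelihood in closed
form (prewhitening each subject block; the first exam enters
untransformed, later exams as $(e_j - \rho e_{j-1})/\sqrt{1-\rho^2}$)
and profiles $\rho$ over $(-0.99, 0.99)$ with `stats::optimize`
(tolerance $10^{-4}$). Design choices:

- **ML, not REML.** Model selection compares AIC across fixed-effect
  sets, which is only coherent under full maximum likelihood. AIC uses
  $p + 2$ parameters (coefficients, $\sigma^2$, $\rho$).
- **AR(1) on exam order, not elapsed time.** Discrete-lag AR(1) is the
  simplest reading of "autoregressive within-subject correlation" for
  irregular visit schedules; a continuous-time kernel would need a
  time-scale parameter the data sources do not pin down.
- **Degenerate cases.** With one exam per subject $\rho$ is
  unidentified and is fixed at 0, reproducing OLS exactly (this is a
  tested invariant, cross-checked against `nlme::gls` on multi-exam
  data).
- **Standard errors** are model-based at $\hat\rho$ with an $n-p$
  variance correction and normal reference; the package draws no
  fine-grained inference from them.

`select_model_aic()` enumerates all $2^k - 1$ non-empty covariate
subsets (k ≤ 10), ranks by AIC, and breaks ties toward fewer variables,
then lexicographically — exhaustive search, not stepwise, so the
reported optimum is the global one.

## Stratified equations and cross-validation

A single log-linear equation cannot capture the nonlinearity of GFR in
creatinine, so equations are fitted separately in eight strata: sex ×
SCR quartiles. Conventions, each of which was a genuinely open choice:

- **Quartiles** use `stats::quantile` type 7 (linear interpolation
  between order statistics), computed at the *examination* level,
  separately per sex. Exam-level quartiles make the stratum counts
  nearly equal in exams, matching how such equations are applied.
- **Intervals** are half-open $[lo, hi)$, bottom stratum $(0, hi)$,
  top $[lo, \infty)$ — every positive SCR belongs to exactly one
  stratum (a property-tested invariant).
- **Within-stratum fits are OLS** on scaled covariates (age/10,
  HbA1c, FPG/100, SCR). These are prediction equations; no
  within-stratum inference is drawn, and OLS matches the prediction
  objective. An AR(1) variant is available via `method = "ar1"`.
- **Diabetes duration is excluded** from the equations (it is
  frequently unknown in practice), although it participates in model
  selection and in the aGFR − eGFR difference model.

`cross_validate()` guards against optimism: subjects (never single
exams) are partitioned into 10 folds differing by at most one subject;
stratum cut points and equations are re-estimated on each training 90 %
(re-estimating cut points per fold keeps the procedure leakage-free at
the cost of slight stratum-boundary wobble between folds); each exam
receives exactly one out-of-fold prediction from a fit that saw none of
that subject's data. The reported final equation averages the ten
training fits stratum by stratum, aligning strata by rank within sex
and averaging the cut points as well.

## Evaluation metrics

- **P30** is the fraction of estimates within 30 % of aGFR, with the
  boundary *inclusive* (|est − aGFR| ≤ 0.30·aGFR); it is scale
  invariant by construction.
- **ROC curves** label hyperfiltration from *measured* aGFR only
  (default rule: strictly greater than 120 mL/min/1.73 m²; the boundary
  comparison is configurable because usage varies between strict and
  non-strict in the literature). Thresholds sweep midpoints between
  adjacent unique scores plus infinite endpoints; AUC is the
  Mann–Whitney statistic with half credit for ties (tested against
  exhaustive pair counting).
- **DeLong's test** compares two correlated AUCs via placement-value
  covariances (tested against `pROC` and against a bootstrap variance).
- **"Accounting for correlation among estimates"** when comparing two
  correlations that share aGFR is implemented as the
  Meng–Rosenthal–Rubin Fisher-z test (Steiger family). This is an
  interpretation of a textbook reference, documented as such. Its $n$
  counts examinations; with ~10 exams per subject the effective sample
  size is smaller, so p-values on longitudinal data are
  anti-conservative. No design-effect correction is applied; treat the
  z as descriptive.

## The synthetic cohort generator

The study data the equations come from are private, so the package
ships `simulate_cohort()`, which emulates the *published description*
of the cohort rather than any real records: 269 subjects, 2798
examinations eligible at CKD-EPI eGFR ≥ 60, about 70 % of exams from
women, mean inter-exam gap 3.3 ± 1.9 years. The generative skeleton
uses the published regression coefficients verbatim:

- 1/SCR (dL/mg) = 1.4931 + 0.2821·female − 0.0082·age + 0.0287·HbA1c
  − 0.0043·FPG/10 + AR(1) residual (per-sex stationary sd 0.29 men /
  0.35 women, set from the published per-sex SCR spreads), floored at
  SCR 0.3 mg/dL;
- log aGFR = 5.8502 − 0.2151·female − 0.0100·age − 0.8639·SCR +
  0.0061·FPG/10 + 0.0061·HbA1c + AR(1) residual (stationary sd 0.237).

FPG and HbA1c are a correlated Gaussian pair (copula correlation 0.71
applied to both the between-subject level and the within-subject AR(1)
innovations, so the exam-level correlation lands near 0.71); covariate
variance splits 2/3 between subjects, 1/3 within; every within-subject
process shares `ar1_rho = 0.6`. Inter-exam gaps are **lognormal** with
mean 3.3 and sd 1.9 years — a >0-truncated normal with those moments
would shift the mean to ≈3.49, so the lognormal (positive by
construction, exact mean) is used instead. Baseline ages are truncated
normal on [18, 60] (recruitment range), with per-sex means 32.4/31.5
chosen so that *exam-level* mean ages land near the published 49.4
(men) / 48.5 (women) after the offset accrued over repeated exams.
Exam counts are uniform on 7..15 per subject; after per-exam
eligibility screening the total is trimmed (dropping last exams of the
most-examined subjects) or topped up (regenerating the sparsest
subjects) to exactly 2798, so headline cohort-size checks are exact.

**Calibration.** The free constants above were fixed once: the
residual sd of log aGFR (0.237) is the value at which the fitted
age+sex+SCR model explains ≈44.8 % of log-aGFR variance (averaged over
five seeds), the stated calibration target, with FPG+HbA1c then adding
≈3 points; the 1/SCR residual sds reproduce the published per-sex SCR
standard deviations. The emergent quantities — mean CKD-EPI eGFR, mean
aGFR − eGFR difference, SCR means — are *not* parameterized anywhere;
they fall out of the published regression skeletons plus the covariate
moments, which is exactly what makes them useful checks.

**What the simulator does not reproduce.** It is a Gaussian
hierarchical sampler, so it cannot honour every published marginal
simultaneously when the published regression coefficients and the
published marginals are not mutually consistent (fitted mixed-model
coefficients under-predict the published marginal mean aGFR by a few
percent, and imply a sex asymmetry in mean aGFR that the published
per-sex means do not show). Its exam-level age spread (sd ≈ 13.5 y) and
diabetes durations (mean ≈ 19 y) are wider/longer than the published
10–11 y and 12.5–13.5 y: with ≈10.4 exams per subject at 3.3-year
gaps, exam-level duration cannot average 13.5 y. No treatment effects,
assay drift, dropout, or informative missingness are simulated.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* (fitting, selection, cross-validation, evaluation) behaves
correctly and recovers known truths — not that the shipped equations
generalise to any real population.

## The shipped equation family

`pima_equations()` returns the published eight-stratum equation set.
Two caveats travel with it. First, the published table does not state
the variable scalings; raw-unit evaluation of its coefficients yields
implausible magnitudes (e.g. −0.1377 per *year* of age), so the
package applies age/10 and FPG/100 — the combination consistent with
the companion regression models (−0.0100/yr ≈ −0.10/decade; 0.0061 per
10 mg/dL ≈ 0.061 per 100 mg/dL). This is an inference, and predictions
from the shipped spec should be treated as provisional; re-deriving
equations on your own cohort with `cross_validate()` is the canonical
route. Second, two typographic anomalies in the source were corrected:
the men's top-stratum HbA1c coefficient "00.328" is encoded as 0.0328,
and its lower bound "−0.90" as 0.90 mg/dL.

## Numerical conventions and problem sizes

- Natural logarithms throughout (the log-aGFR intercept ≈ 5.85 ≈
  ln 130 plus offsets is only coherent in base e).
- Eligibility: exams with criterion value ≥ 60 are retained ("< 60
  excluded" is strict); the filter is idempotent and re-sequences exam
  indices.
- Equation specs serialize to a flat text format with `%.17g` numbers,
  so write→read round trips are bit-exact; stratum partitions are
  re-validated on read.
- Fold assignment requires an explicit seed and restores the caller's
  RNG state; simulation is deterministic given a seed.
- The test suite exercises full-size cohorts (269 × 2798) for
  calibration and pipeline checks, 20 seeds for parameter recovery,
  1000 null replicates for test-size checks, and a 2000-replicate
  bootstrap for the DeLong variance oracle; smaller cohorts (40–150
  subjects) are used where full size adds nothing.

## Known limitations

- The shipped equations' scalings are inferred, not published
  (above).
- The dependent-correlation test ignores within-subject clustering.
- The simulator's internal consistency trade-offs (age spread,
  duration, per-sex aGFR asymmetry) are documented above; calibration
  tests pin the directly parameterized moments tightly and the emergent
  ones at honest, wider tolerances.
- Cystatin-C equations, the 2021 CKD-EPI refit, pediatric equations,
  race-term variants, and non-mg/dL unit systems are out of scope.
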