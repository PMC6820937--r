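# glycogfr

Glycemia-aware approximation of measured GFR in type 2 diabetes.

## The problem

Creatinine-based estimating equations (CKD-EPI, MDRD) are the clinical
standard for glomerular filtration rate, but in people with type 2
diabetes they systematically underestimate the *measured*, body-surface-
area-indexed GFR (aGFR = iothalamate clearance / BSA × 1.73), and the
underestimation worsens exactly where it matters for detecting renal
**hyperfiltration** (aGFR > 120 mL/min/1.73 m²), a putative early marker
of diabetic kidney injury. One reason is that creatinine carries no
information about glycemia, yet fasting plasma glucose (FPG) and HbA1c
drive filtration up.

`glycogfr` is a toolkit for building and evaluating *approximating
equations* that add glycemia to the usual covariates. It provides:

- **Closed-form equations** — Du Bois BSA, CKD-EPI (2009, non-black
  constants), MDRD, and a shipped eight-stratum glycemia-aware equation
  family of the form

  aGFR ≈ exp( b₀ + b₁·age/10 + b₂·HbA1c + b₃·FPG/100 + b₄·SCR ),

  with separate coefficients per sex × serum-creatinine-quartile stratum.
- **A derivation pipeline** — marginal linear models with AR(1)
  within-subject correlation (ML, profile likelihood on ρ), exhaustive
  AIC model selection over covariate subsets, sex-by-SCR-quartile
  stratified fits, and subject-level 10-fold cross-validation with
  stratum-wise coefficient averaging.
- **Evaluation metrics** — Pearson r/r², RMSE, bias by GFR level, P30
  (fraction of estimates within ±30 % of aGFR), a Steiger/Meng test for
  dependent overlapping correlations, and ROC/AUC with the DeLong test
  for correlated ROC areas.
- **A synthetic cohort generator** — a calibrated longitudinal simulator
  (269 subjects, 2798 eligible examinations, exams with eGFR < 60
  excluded) whose generative skeleton is the published pair of
  mixed-model regressions for 1/SCR and log aGFR, with a Gaussian copula
  tying FPG to HbA1c (r ≈ 0.71) and AR(1) persistence within subject.
  The real study data are private; the simulator makes the whole
  pipeline testable.

## Worked example

```r
library(glycogfr)

cohort <- simulate_cohort(generative_config(), seed = 1)  # 2798 exams, 269 subjects
egfr   <- ckd_epi(cohort$sex, cohort$age, cohort$scr)

## derive glycemia-aware equations with subject-level 10-fold CV
cv <- cross_validate(cohort, k = 10, seed = 1)

evaluate_estimator(cohort, cv$oof_predictions)
#> n = 2798: r = 0.640 (r^2 = 0.410), RMSE = 32.89, bias (aGFR - est) = 3.73, P30 = 77.7%
evaluate_estimator(cohort, egfr)
#> n = 2798: r = 0.610 (r^2 = 0.372), RMSE = 42.00, bias (aGFR - est) = 23.70, P30 = 71.1%

compare_dependent_correlations(cohort$agfr, cv$oof_predictions, egfr)
#> r1 = 0.640 vs r2 = 0.610 (r12 = 0.908, n = 2798): z = 4.911, p = 9.06e-07

delong_compare(cohort$agfr, cv$oof_predictions, egfr)
#> DeLong: AUC1 = 0.8114 vs AUC2 = 0.7978, z = 3.551, p = 0.000383

threshold_at_specificity(roc_curve(cohort$agfr, egfr), 0.80)$threshold
#> [1] 108.1995
```

Reading: on a synthetic cohort the cross-validated glycemia-aware
equations track measured aGFR more closely than CKD-EPI (higher r, P30
up six points), remove almost all of the systematic underestimation
(mean bias 3.7 vs 23.7 mL/min/1.73 m²), and discriminate hyperfiltration
better (AUC 0.811 vs 0.798; at 80 % specificity the CKD-EPI screening
threshold sits near 108 mL/min/1.73 m², far below the 120 definition).
The out-of-fold predictions are produced by equations fitted without any
of that subject's data, so the comparison carries no overfitting
advantage.

The shipped published equation family is available as
`pima_equations()`; note its variable scalings are an inference (see
`?pima_equations`), and re-derivation via `cross_validate()` on your own
cohort is the recommended route.

A thin command-line interface wraps the same functions
(`simulate`, `fit`, `evaluate`, `predict` subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","glycogfr",package="glycogfr"))')" \
  simulate --seed 5 --out cohort.csv
```

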