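---
title: "Methods: baseline comorbidity risk and BMI-attributable excess mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline comorbidity risk and BMI-attributable excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmirisk)
```

## The question and the approach

Whether body mass index (BMI) predicts all-cause mortality once
comorbidities are accounted for is the core of the "obesity paradox"
literature: in many comorbid cohorts, overweight and mildly obese subjects
appear to survive as well as or better than "normal"-weight subjects.
`bmirisk` implements one way of separating the two signals:

1. **Baseline risk model.** Fit a logistic regression of the 8-year
   all-cause death indicator on age, sex and dichotomous Elixhauser-style
   comorbidity flags. BMI and the obesity flag are *excluded by
   construction* (`fit_logistic()` refuses them), so the model captures only
   comorbidity- and demography-attributable risk.
2. **Risk stratification.** Rank subjects by predicted risk and cut at the
   50th, 75th, 90th and 95th percentiles into five groups (Low, Medium,
   MediumHigh, High, VeryHigh). Comorbidity burden, not BMI, drives group
   membership.
3. **Raw rates by BMI category.** Tabulate deaths / subjects in 5-unit BMI
   categories from <15 to >=45 kg/m², overall and per risk group. The
   deliberately non-WHO categories avoid presupposing where "normal" ends.
4. **Smoothed curves.** Treat BMI as continuous on a grid from 15 to 55 by
   0.5 kg/m² and estimate the mortality rate at each grid point by
   Nadaraya–Watson kernel regression of the binary outcome,
   \( \hat m(b) = \sum_i K\!\big(\tfrac{b_i - b}{h}\big) y_i \big/
      \sum_i K\!\big(\tfrac{b_i - b}{h}\big) \),
   with a Gaussian kernel and bandwidth \(h = 0.5\) kg/m².
5. **Excess risk.** For each subject form the residual
   \(r_i = y_i - \hat p_i\) (observed outcome minus model-predicted risk)
   and smooth it over BMI the same way. Because the logistic score equation
   forces the residuals to average zero over the fitting cohort, any
   systematic drift of the smoothed residual against BMI is mortality risk
   the comorbidity model does not explain — the BMI-attributable excess.
6. **Uncertainty.** Every curve carries an empirical 95% band: the
   2.5th/97.5th percentiles of the estimator over 200 bootstrap resamples
   of subjects, drawn with replacement within the stratum being curved.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every
stage is testable end to end. The default configuration emulates the
published reference cohort (N = 39,739; mean age 52.6, range 18–89; 38.1%
male; 8-year mortality 11.86%):

* **Age** — truncated normal, mean 52.6 y, bounds 18/89. Only the mean and
  range were published; the default sd of 16 y spreads ages across the
  published range without piling mass on the truncation bounds.
* **Sex** — Bernoulli(0.381).
* **Comorbidities** — each flag is Bernoulli with an age-dependent logit
  `a_j + b_j * age`. The slope `b_j` was calibrated once per comorbidity by
  a weighted logistic fit of the published prevalence-by-risk-group
  gradient against the groups' mean ages, and the intercept `a_j` is solved
  at generation time (`calibrate_prevalence_intercept()`, root-finding to
  1e-8) so the marginal prevalence matches the published entire-cohort
  value exactly in expectation. Flags are independent *given age*; the
  shared age dependence is the only source of comorbidity correlation.
  Richer dependence (copulas, disease cascades) is deliberately out of
  scope: the published tables document prevalence gradients, not pairwise
  correlations.
* **BMI** — truncated normal, bounds 12/60, drawn independently of the
  comorbidities (the published BMI distributions are near-identical across
  risk groups). Mean 28.4 and sd 6.4 kg/m² were fit once by maximum
  likelihood to the published BMI-category counts.
* **Death** — Bernoulli with logit
  `-8.112 + 0.082*age + 0.231*male + sum(coef_j * flag_j) + u(bmi)`, using
  the published model coefficients, plus a model-external BMI effect
  `u(bmi) = s_lo * max(0, 20 - bmi) + s_hi * max(0, bmi - 40)` with default
  slopes 0.15 log-odds per kg/m². Two hinges with a flat stretch between
  the knots create the published U-with-plateau shape; the fitted model
  never sees BMI, so the injected effect must surface in the residual
  curve — a generative truth the tests recover. Setting both slopes to 0
  gives a null cohort for flatness checks.

What the generator does **not** emulate: the right skew of real BMI (a
truncated normal puts ~0.5% of subjects above 45 kg/m² where the real
cohort had 2.5%), longitudinal BMI measurements, medications, smoking,
censoring, and between-comorbidity correlation beyond age. Passing tests
therefore demonstrate that the *machinery* recovers known truth under the
stated mechanism, not that the mechanism is a complete model of the
reference population.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `alpha` | 0.05 | — | Wald backwards-elimination threshold; one covariate removed per step, largest p first. The published analysis names backwards elimination without a criterion; Wald at 0.05 is the era's convention. Sign is never considered — a collinearity-flipped but significant covariate (hyperlipidemia in the reference model) is retained. |
| `min_cases` | 5 | subjects | Binary covariates with fewer positive cases are dropped pre-fit (they invite separation; the reference cohort's HIV/AIDS flag rounds to 0.0% prevalence) and logged. |
| `percentiles` | 50/75/90/95 | % | Risk-group cuts; realized thresholds use the linear-interpolation quantile (type 7). Ties at a threshold fall in the lower group — the published group sizes show ties were broken somehow, but not how; this rule is simply fixed and documented. |
| `bandwidth` | 0.5 | kg/m² | Published for the residual curves; adopted for the rate curves too, which share the same grid and framing. |
| `n_boot` | 200 | resamples | Published bootstrap iteration count. |
| `mass_threshold` | 1.0 | subjects | The kernel is used in unit-height form, so the weight mass at a grid point is the equivalent number of co-located subjects; points below one subject's worth of mass are flagged undefined rather than extrapolated, because the extreme-BMI tails are sparse and estimates there are dominated by a handful of subjects. The numeric value is still reported where computable, with `defined = FALSE`. |

## Numerical choices

* Logistic fits are IRLS (`stats::glm`, binomial), convergence
  `|Δ logLik| < 1e-8`, at most 100 iterations. An optional ridge
  (`ridge = 1e-6` is a sensible rescue value) is available for degenerate
  designs and is always recorded in the returned object.
* Quasi-separation (any |coefficient| > 15) raises a warning but still
  returns the fit, since elimination or the rare-case guard usually
  resolves it.
* Predicted risks are clamped to the open interval (0, 1) at machine
  precision, keeping residuals strictly inside (−1, 1).
* The bootstrap band stores the full-sample estimate as the point
  estimate; the bootstrap mean is kept alongside for plotting (published
  figures plot both). Grid points where the full-sample estimate falls
  outside the bootstrap draw range are flagged in an attribute instead of
  being silently clipped.
* The per-subject residual sign is observed − predicted, so that values
  above zero mean *excess* mortality. The published text defines the
  residual the other way around while its figures interpret positive as
  increased risk; the figure convention is the one implemented.
* An empty BMI category reports `rate = NA`, never 0/0 = 0.
* `run_all()` derives per-stage seeds from one master seed by fixed
  offsets, so a stage can be re-run in isolation and identical
  config + seed reproduces byte-identical outputs (MD5s in the manifest).

## Test problem sizes

The package validates itself on simulation sizes chosen to make the
statistical assertions sharp while keeping the default suite quick:
marginal calibration and coefficient recovery use cohorts of 50,000
subjects (coefficient recovery across 20 seeds asserts ≥95% of estimates
within 3 SEs of truth); U-shape recovery uses 50,000 subjects with the
default hinge effect and a null run with slopes 0; bootstrap coverage uses
100 replications of n = 2,000 at a single central grid point; kernel
estimates are checked against a brute-force loop oracle on 100 random
instances of up to 200 subjects at 1e-12.

## Known limitations

* The synthetic mechanism cannot reproduce real-data quantities that
  depend on the reference cohort's joint distribution — the per-risk-group
  rate table cells, the exact real AUC of 0.91 (the synthetic default
  lands near 0.89), or the real group-size tie structure.
* The truncated-normal BMI underweights the extreme-obesity tail, so
  high-BMI grid points carry less mass than in the real cohort and their
  bands are wide.
* The pipeline models a fixed 8-year binary endpoint; there is no
  censoring and no time-to-event component.
* Backwards elimination is the published selection rule, kept for
  fidelity; it inherits that rule's known instability under collinearity.
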