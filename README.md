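# bmirisk

Does body mass index still predict all-cause mortality once comorbidities
are taken into account? In comorbid cohorts, overweight and mildly obese
subjects often survive as well as or better than "normal"-weight subjects —
the so-called obesity paradox. `bmirisk` implements an analysis pipeline
for this question, aimed at epidemiologists and biostatisticians working
with fixed-horizon cohort data: a comorbidity-based baseline mortality risk
model, percentile risk stratification, BMI-category mortality tables, and
kernel-smoothed mortality and excess-risk curves with bootstrap confidence
bands — together with a calibrated synthetic cohort generator so the whole
pipeline runs and validates without patient data.

## The method

Given a cohort with age, sex, dichotomous Elixhauser-style comorbidity
flags, mean BMI and an 8-year death indicator `y`:

1. **Baseline risk.** Logistic regression
   `logit P(y = 1) = β₀ + β_age·age + β_male·male + Σⱼ βⱼ·flagⱼ`,
   with BMI and the obesity flag excluded by construction, followed by
   backwards elimination on Wald p-values (drop the largest p > α = 0.05,
   one covariate per step). Binary covariates with fewer than 5 positive
   cases are dropped pre-fit.
2. **Risk groups.** Subjects are cut at the 50th/75th/90th/95th
   percentiles of predicted risk p̂ into Low, Medium, MediumHigh, High and
   VeryHigh strata.
3. **Raw rates.** Deaths / subjects per 5-unit BMI category (<15 up to
   ≥45 kg/m²), overall and per risk group.
4. **Smoothed curves.** Nadaraya–Watson estimate on a BMI grid (15–55 by
   0.5 kg/m²), Gaussian kernel, bandwidth h = 0.5 kg/m²:
   m̂(b) = Σᵢ K((bmiᵢ−b)/h)·yᵢ / Σᵢ K((bmiᵢ−b)/h).
5. **Excess risk.** Per-subject residual rᵢ = yᵢ − p̂ᵢ smoothed the same
   way: the mortality not explained by comorbidities, as a function of
   BMI. Positive means excess mortality.
6. **Bands.** Empirical 95% percentile bands from 200 bootstrap resamples
   of subjects within each stratum.

The synthetic generator draws age-dependent comorbidity flags calibrated
to published cohort marginals, uses the published mortality coefficients
(intercept −8.112, age 0.082/y, male 0.231, 25 comorbidity terms), and
injects a U-shaped BMI effect through two hinge terms (knots 20 and
40 kg/m²) that the fitted model never sees — so the residual curve has a
known truth to recover.

## Worked example

```r
library(bmirisk)

cfg    <- synthetic_config(n_subjects = 10000, seed = 42)
cohort <- generate_cohort(cfg)
model  <- backwards_eliminate(cohort,
                              c("age", "male", comorbidity_names(cohort)),
                              alpha = 0.05)
risks  <- predict_risk(model, cohort)
compute_auc(risks, cohort$death_8y)
#> [1] 0.894

groups <- assign_risk_groups(risks)
groups
#> Percentile risk groups
#>        Low     Medium MediumHigh       High   VeryHigh
#>       5000       2500       1500        500        500
#> Cut points (risk scale):
#>     p50     p75     p90     p95
#> 0.03212 0.10340 0.31150 0.53290

head(format_rate_table(categorical_rate_table(cohort, groups)), 8)
#>         group category    n deaths  rate
#>  EntireCohort      <15  117     19 0.162
#>  EntireCohort   15-<20  760     94 0.124
#>  EntireCohort   20-<25 2047    216 0.106
#>  EntireCohort   25-<30 3038    316 0.104
#>  EntireCohort   30-<35 2511    262 0.104
#>  EntireCohort   35-<40 1199    113 0.094
#>  EntireCohort   40-<45  289     39 0.135
#>  EntireCohort     >=45   39      8 0.205

resid <- compute_residuals(cohort$death_8y, risks)
curve <- kernel_residual_curve(cohort$bmi, resid, n_boot = 200, seed = 43)
round(curve[curve$grid %in% c(16, 25, 30, 35, 50), 1:5], 4)
#>  grid estimate boot_mean ci_lower ci_upper
#>    16   0.0472    0.0488   0.0087   0.0961
#>    25  -0.0023   -0.0022  -0.0151   0.0136
#>    30  -0.0056   -0.0056  -0.0196   0.0083
#>    35   0.0016    0.0021  -0.0148   0.0203
#>    50  -0.0580   -0.0563  -0.1014  -0.0137
```

Reading the output: the model discriminates well (AUC 0.894) using
comorbidities alone; the five risk groups split exactly 50/25/15/5/5% of
subjects at the realized risk cut points; the raw category rates show the
U shape with a flat nadir (10–11% mortality across BMI 20–40, higher at
both extremes). The excess-risk curve is significantly positive at BMI 16
(band above zero: more deaths at very low BMI than comorbidities explain)
and flat near zero across the 25–35 nadir. At BMI 50 this 10,000-subject
cohort has only a handful of subjects — at that size the band is wide and
can sit below zero; at the default cohort size (n = 39,739, see below) the
high-BMI excess emerges. `plot(curve, zero_line = TRUE)` draws the curve
with its band.

A full seeded run — cohort CSV, model JSON, group assignments, rate table,
all curve CSVs and a manifest with output hashes — is one call:

```r
run_all(run_config(out_dir = "out", seed = 1))
```

or from the shell via the thin CLI wrapper:

```sh
exec/bmirisk run-all --seed 1 --out out/
exec/bmirisk simulate --seed 42 --out cohort.csv
exec/bmirisk fit --cohort cohort.csv --alpha 0.05 --out model.json
```

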