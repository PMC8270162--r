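#' Reference mortality-model coefficients and comorbidity prevalences
#'
#' Published baseline characteristics of the Olmsted County reference cohort
#' (N = 39,739; mean age 52.6 years, range 18-89; 38.1% male; 11.86% 8-year
#' all-cause mortality) together with the log-odds coefficients of its
#' comorbidity-based mortality risk model. These values parameterize the
#' default synthetic cohort: `prevalence` is the entire-cohort marginal
#' prevalence of each Elixhauser-style flag, `coefficient` its log-odds
#' effect on 8-year death, and `age_slope` the per-year log-odds gradient
#' used to make prevalence rise with age (calibrated once to the published
#' prevalence-by-risk-group gradient; see the package vignette).
#'
#' The obesity flag is deliberately absent: the baseline risk model excludes
#' any direct BMI effect so that BMI-attributable excess risk can be read
#' from the model residuals.
#'
#' @return A data frame with columns `name`, `prevalence` (proportion in
#'   (0,1)), `age_slope` (per-year log-odds) and `coefficient` (log-odds).
#'   Row order is the canonical comorbidity-column order used in cohort CSVs.
#' @seealso [synthetic_config()], [reference_intercept()]
#' @export
#' @examples
#' head(elixhauser_defaults())
elixhauser_defaults <- function() {
  # name, entire-cohort prevalence, per-year log-odds age slope, death log-odds
  d <- rbind(
    c("hyperlipidemia",                 0.3960, 0.0392, -0.584),
    c("hypertension",                   0.3710, 0.0817,  0.132),
    c("chronic_lung_disease",           0.1990, 0.0295,  0.452),
    c("deficiency_anemia",              0.1420, 0.0589,  0.232),
    c("psychoses",                      0.1110, 0.0150,  0.372),
    c("fluid_electrolyte_disorder",     0.1050, 0.0812,  0.555),
    c("coronary_artery_disease",        0.1370, 0.0982,  0.342),
    c("valvular_disease",               0.0950, 0.0714,  0.196),
    c("other_neurological_disorders",   0.0760, 0.0693,  0.754),
    c("diabetes_mellitus",              0.1050, 0.0617,  0.442),
    c("peripheral_vascular_disorder",   0.0640, 0.0975,  0.410),
    c("solid_tumor_without_metastasis", 0.0740, 0.0736,  0.400),
    c("weight_loss",                    0.0360, 0.0598,  0.562),
    c("congestive_heart_disease",       0.0460, 0.2002,  0.860),
    c("alcohol_abuse",                  0.0340, 0.0210,  0.622),
    c("chronic_kidney_disease",         0.0220, 0.1208,  0.612),
    c("pulmonary_circulation_disorder", 0.0240, 0.0956,  0.291),
    c("coagulopathy",                   0.0240, 0.0645,  0.485),
    c("liver_disease",                  0.0210, 0.0341,  0.507),
    c("stroke",                         0.0180, 0.1206,  0.251),
    c("drug_abuse",                     0.0180, 0.0072,  0.755),
    c("metastatic_cancer",              0.0170, 0.1119,  1.212),
    c("paralysis",                      0.0150, 0.0795,  0.744),
    c("lymphoma",                       0.0080, 0.0662,  0.588),
    c("hiv_aids",                       0.0005, 0.0322,  1.810)
  )
  data.frame(name = d[, 1],
             prevalence = as.numeric(d[, 2]),
             age_slope = as.numeric(d[, 3]),
             coefficient = as.numeric(d[, 4]),
             stringsAsFactors = FALSE)
}

#' Reference demographic coefficients of the baseline mortality model
#'
#' Intercept and demographic log-odds terms of the published 8-year
#' mortality risk model: intercept -8.112, age 0.082 per year, male 0.231.
#'
#' @return Named numeric vector with elements `intercept`, `age`, `male`.
#' @export
reference_intercept <- function() {
  c(intercept = -8.112, age = 0.082, male = 0.231)
}

#' Full default coefficient map for the synthetic mortality mechanism
#'
#' @return Named numeric vector: `age`, `male`, then one log-odds
#'   coefficient per comorbidity in canonical order.
#' @keywords internal
default_true_coefficients <- function() {
  ref <- reference_intercept()
  ex <- elixhauser_defaults()
  c(ref[c("age", "male")], setNames(ex$coefficient, ex$name))
}
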