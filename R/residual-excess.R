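#' Per-subject excess-risk residuals
#'
#' Residual of the baseline mortality model for each subject:
#' `r_i = y_i - p_i` (observed 8-year outcome minus model-predicted risk).
#' Positive values mean more deaths than the comorbidity model explains —
#' excess mortality — and negative values mean fewer. Over the model's own
#' fitting cohort the residuals average to zero (the logistic score
#' equation), so any systematic drift of the smoothed residual against BMI
#' is risk the baseline covariates do not account for.
#'
#' @param outcomes 0/1 outcome vector.
#' @param risks Predicted risks from [predict_risk()], aligned with
#'   `outcomes`.
#' @return Numeric residual vector in (-1, 1), carrying the model
#'   `fingerprint` attribute of `risks` if present.
#' @export
compute_residuals <- function(outcomes, risks) {
  if (length(outcomes) != length(risks))
    stop("outcomes and risks must have equal length", call. = FALSE)
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be 0/1", call. = FALSE)
  if (any(risks <= 0 | risks >= 1))
    stop("risks must lie strictly in (0, 1)", call. = FALSE)
  r <- as.numeric(outcomes) - as.numeric(risks)
  attr(r, "fingerprint") <- attr(risks, "fingerprint")
  r
}

#' Kernel-smoothed excess-risk curve over BMI
#'
#' Applies the same Nadaraya-Watson machinery as [kernel_rate_curve()] to
#' excess-risk residuals, with a percentile bootstrap band. The zero line
#' is the reference: band segments above zero indicate BMI regions with
#' mortality in excess of what the baseline comorbidity model predicts for
#' those subjects; segments below zero indicate lower-than-predicted
#' mortality.
#'
#' @param bmi BMI values (kg/m^2) aligned with `residuals`.
#' @param residuals Residuals from [compute_residuals()].
#' @inheritParams bootstrap_band
#' @return A `smoothed_curve` (see [bootstrap_band()]).
#' @export
kernel_residual_curve <- function(bmi, residuals, grid = bmi_grid(),
                                  bandwidth = 0.5, n_boot = 200,
                                  seed = 1L, mass_threshold = 1.0) {
  if (any(residuals <= -1 | residuals >= 1))
    stop("residuals must lie strictly in (-1, 1)", call. = FALSE)
  bootstrap_band(kernel_rate_curve, bmi, residuals, grid = grid,
                 bandwidth = bandwidth, n_boot = n_boot, seed = seed,
                 mass_threshold = mass_threshold)
}

#' Smoothed residual curves per risk group
#'
#' Residual analogue of [curves_by_group()]: the model is fitted once on
#' the whole cohort, and each risk group's curve uses that group's own
#' subjects with the global model's residuals.
#'
#' @param cohort Cohort table.
#' @param residuals Residuals from [compute_residuals()], aligned with
#'   `cohort`.
#' @param groups Optional [assign_risk_groups()] result.
#' @inheritParams curves_by_group
#' @return Named list of `smoothed_curve` objects.
#' @export
residual_curves_by_group <- function(cohort, residuals, groups = NULL,
                                     grid = bmi_grid(), bandwidth = 0.5,
                                     n_boot = 200, seed = 1L,
                                     mass_threshold = 1.0) {
  curves_by_group(cohort, groups, outcomes = residuals, grid = grid,
                  bandwidth = bandwidth, n_boot = n_boot, seed = seed,
                  mass_threshold = mass_threshold)
}
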