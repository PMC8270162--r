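#' Write a cohort table to CSV
#'
#' Canonical column order: `subject_id`, `age`, `male`, the comorbidity
#' flags in table order, `bmi`, `death_8y`. Flags are written as 0/1 and
#' continuous columns at full precision (well beyond 4 decimal digits), so
#' a write-read round trip is value-identical.
#'
#' @param cohort Cohort table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "age", "male", comorbidity_names(cohort),
            "bmi", "death_8y")
  df <- as.data.frame(cohort)[, cols]
  df$age <- sprintf("%.10g", df$age)
  df$bmi <- sprintf("%.10g", df$bmi)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a cohort CSV
#'
#' Schema-checked load of a patient-level cohort file: requires columns
#' `subject_id`, `age`, `male`, `bmi`, `death_8y` plus zero or more 0/1
#' comorbidity flag columns; refuses missing values, non-binary flags
#' (naming the column and first offending row) and BMI outside
#' (5, 100) kg/m^2. Prints a one-paragraph summary (rows, death rate, BMI
#' range, per-flag prevalence) unless `quiet = TRUE`.
#'
#' @param path CSV file path.
#' @param quiet Suppress the summary printout.
#' @return A `cohort_table` data frame.
#' @export
validate_cohort_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "male", "bmi", "death_8y")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort CSV lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  flags <- setdiff(names(df), required)
  for (nm in c("age", "male", "bmi", "death_8y", flags)) {
    if (anyNA(df[[nm]]))
      stop(sprintf("column '%s' has missing values (first at row %d)",
                   nm, which(is.na(df[[nm]]))[1L]), call. = FALSE)
    if (!is.numeric(df[[nm]]))
      stop(sprintf("column '%s' is not numeric", nm), call. = FALSE)
  }
  for (nm in c("male", "death_8y", flags)) {
    bad <- which(!df[[nm]] %in% c(0, 1))
    if (length(bad))
      stop(sprintf("column '%s' must be 0/1; value %s at row %d",
                   nm, format(df[[nm]][bad[1L]]), bad[1L]), call. = FALSE)
  }
  bad_bmi <- which(df$bmi <= 5 | df$bmi >= 100)
  if (length(bad_bmi))
    stop(sprintf("column 'bmi' outside (5, 100) kg/m^2 at row %d (%.2f)",
                 bad_bmi[1L], df$bmi[bad_bmi[1L]]), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("column 'subject_id' has duplicates", call. = FALSE)
  cohort <- as_cohort_table(df, comorbidities = flags)
  if (!quiet) {
    cat(sprintf(
      "cohort: %d subjects; death rate %.4f; BMI %.1f-%.1f kg/m^2; %d flags\n",
      nrow(df), mean(df$death_8y), min(df$bmi), max(df$bmi), length(flags)))
    if (length(flags)) {
      prev <- vapply(flags, function(nm) mean(df[[nm]]), numeric(1))
      cat(paste(sprintf("  %s: %.3f", flags, prev), collapse = "\n"), "\n")
    }
  }
  cohort
}

#' Write a smoothed curve to CSV
#'
#' Columns: `grid`, `estimate`, `boot_mean`, `ci_lower`, `ci_upper`,
#' `mass`, `defined`.
#'
#' @param curve A `smoothed_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Either a [synthetic_config()]
#' (the default) or a path to an external cohort CSV may supply the cohort.
#'
#' @param out_dir Output directory (created if needed).
#' @param synthetic A [synthetic_config()]; ignored when `cohort_csv` is
#'   given.
#' @param cohort_csv Optional path to an existing cohort CSV.
#' @param alpha Backwards-elimination threshold; default 0.05.
#' @param percentiles Risk-group percentile cuts; default
#'   `c(0.5, 0.75, 0.9, 0.95)`.
#' @param breakpoints BMI category breakpoints; default 15..45 by 5.
#' @param grid BMI evaluation grid; default [bmi_grid()].
#' @param bandwidth Kernel bandwidth (kg/m^2); default 0.5.
#' @param n_boot Bootstrap iterations; default 200.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param min_cases Rare-covariate guard for the model fit.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synthetic = synthetic_config(),
                       cohort_csv = NULL,
                       alpha = 0.05,
                       percentiles = c(0.5, 0.75, 0.9, 0.95),
                       breakpoints = c(15, 20, 25, 30, 35, 40, 45),
                       grid = bmi_grid(),
                       bandwidth = 0.5,
                       n_boot = 200,
                       seed = 1L,
                       min_cases = 5) {
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L)
    stop("invalid run config: field 'out_dir' must be a single path",
         call. = FALSE)
  if (!is.null(cohort_csv) && !file.exists(cohort_csv))
    stop("invalid run config: field 'cohort_csv' path does not exist",
         call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("invalid run config: field 'bandwidth' must be positive",
         call. = FALSE)
  if (!is.numeric(n_boot) || n_boot < 2)
    stop("invalid run config: field 'n_boot' must be >= 2", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("invalid run config: field 'alpha' must lie in (0, 1]",
         call. = FALSE)
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 cohort_csv = cohort_csv, alpha = alpha,
                 percentiles = percentiles, breakpoints = breakpoints,
                 grid = grid, bandwidth = bandwidth, n_boot = n_boot,
                 seed = as.integer(seed), min_cases = min_cases),
            class = "run_config")
}

#' Read a synthetic-cohort configuration from JSON
#'
#' Accepts a JSON object whose fields mirror the arguments of
#' [synthetic_config()] (`comorbidity_specs` as an array of
#' `{name, prevalence, age_slope}` records, `true_coefficients` as a
#' name-to-value object, `bmi_effect` as an object with the four hinge
#' fields). Unknown fields are rejected; every supplied field is validated
#' and errors name the offending field. Omitted fields keep package
#' defaults.
#'
#' @param path JSON file path.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(synthetic_config))
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(obj$comorbidity_specs))
    obj$comorbidity_specs <- as.data.frame(obj$comorbidity_specs)
  if (!is.null(obj$true_coefficients))
    obj$true_coefficients <- unlist(obj$true_coefficients)
  if (!is.null(obj$bmi_effect)) obj$bmi_effect <- as.list(obj$bmi_effect)
  do.call(synthetic_config, obj)
}

# Per-stage seeds derived from the master seed; offsets keep every derived
# seed a valid 32-bit integer for small master seeds.
stage_seeds <- function(master) {
  master <- as.integer(master) %% 1000000L
  c(simulate = master,
    curves = master + 1000003L,
    residuals = master + 2000003L)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> fit + backwards elimination -> percentile
#' stratification -> BMI category rate table -> smoothed mortality curves
#' -> residual excess-risk curves, writing every artefact under
#' `config$out_dir`:
#' `cohort.csv`, `model.json`, `groups.csv`, `table2.csv`,
#' `curves_<stratum>.csv`, `residual_curves_<stratum>.csv` and
#' `manifest.json` (inputs, derived seeds, package version, MD5 hash of
#' every output). Identical config + seed reproduces identical hashes. A
#' stage failure aborts with the stage name and leaves a `FAILED` marker
#' file naming the stage.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  stage <- "simulate"
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   alpha = config$alpha, bandwidth = config$bandwidth,
                   n_boot = config$n_boot,
                   package_version =
                     as.character(utils::packageVersion("bmirisk")),
                   stages = character(0), outputs = list())
  fail <- function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    # -- simulate / load ---------------------------------------------------
    if (is.null(config$cohort_csv)) {
      cfg <- config$synthetic
      cfg$seed <- seeds[["simulate"]]
      cohort <- generate_cohort(cfg)
    } else {
      cohort <- validate_cohort_csv(config$cohort_csv, quiet = TRUE)
    }
    path_cohort <- file.path(config$out_dir, "cohort.csv")
    write_cohort_csv(cohort, path_cohort)
    manifest$n_subjects <- nrow(cohort)
    manifest$death_rate <- mean(cohort$death_8y)
    manifest$stages <- c(manifest$stages, "simulate")

    # -- fit ---------------------------------------------------------------
    stage <- "fit"
    covars <- c("age", "male", comorbidity_names(cohort))
    model <- backwards_eliminate(cohort, covars, alpha = config$alpha,
                                 min_cases = config$min_cases)
    path_model <- file.path(config$out_dir, "model.json")
    write_model_json(model, path_model)
    manifest$n_covariates_retained <- length(model$covariates)
    manifest$n_covariates_dropped <- nrow(model$dropped_covariates)
    manifest$stages <- c(manifest$stages, "fit")

    # -- stratify ----------------------------------------------------------
    stage <- "stratify"
    risks <- predict_risk(model, cohort)
    groups <- assign_risk_groups(risks, probs = config$percentiles)
    path_groups <- file.path(config$out_dir, "groups.csv")
    gdf <- data.frame(subject_id = cohort$subject_id,
                      risk = sprintf("%.10g", risks),
                      group = as.character(groups$group))
    write.csv(gdf, path_groups, row.names = FALSE, quote = FALSE)
    manifest$auc <- compute_auc(risks, cohort$death_8y)
    manifest$group_sizes <- as.list(setNames(as.integer(groups$group_sizes),
                                             names(groups$group_sizes)))
    manifest$stages <- c(manifest$stages, "stratify")

    # -- category table ----------------------------------------------------
    stage <- "rates"
    scheme <- bmi_category_scheme(config$breakpoints)
    tab <- categorical_rate_table(cohort, groups, scheme)
    path_tab <- file.path(config$out_dir, "table2.csv")
    write.csv(format_rate_table(tab), path_tab, row.names = FALSE,
              quote = FALSE)
    manifest$stages <- c(manifest$stages, "rates")

    # -- smoothed mortality curves ----------------------------------------
    stage <- "curves"
    curves <- curves_by_group(cohort, groups, grid = config$grid,
                              bandwidth = config$bandwidth,
                              n_boot = config$n_boot,
                              seed = seeds[["curves"]])
    paths_curves <- character()
    for (nm in names(curves)) {
      p <- file.path(config$out_dir, sprintf("curves_%s.csv", nm))
      write_curve_csv(curves[[nm]], p)
      paths_curves <- c(paths_curves, p)
    }
    manifest$stages <- c(manifest$stages, "curves")

    # -- residual excess-risk curves --------------------------------------
    stage <- "residuals"
    resid <- compute_residuals(cohort$death_8y, risks)
    rcurves <- residual_curves_by_group(cohort, resid, groups,
                                        grid = config$grid,
                                        bandwidth = config$bandwidth,
                                        n_boot = config$n_boot,
                                        seed = seeds[["residuals"]])
    paths_rcurves <- character()
    for (nm in names(rcurves)) {
      p <- file.path(config$out_dir, sprintf("residual_curves_%s.csv", nm))
      write_curve_csv(rcurves[[nm]], p)
      paths_rcurves <- c(paths_rcurves, p)
    }
    manifest$residual_defined_fraction <- lapply(rcurves, function(cv)
      mean(cv$defined))
    manifest$stages <- c(manifest$stages, "residuals")

    outs <- c(path_cohort, path_model, path_groups, path_tab,
              paths_curves, paths_rcurves)
    manifest$outputs <- as.list(setNames(unname(tools::md5sum(outs)),
                                         basename(outs)))
    path_manifest <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, path_manifest, auto_unbox = TRUE,
                         digits = NA)
    unlink(file.path(config$out_dir, "FAILED"))
    invisible(manifest)
  }, error = fail)
}
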