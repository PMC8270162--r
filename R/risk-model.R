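#' Fit the baseline 8-year mortality logistic model
#'
#' Maximum-likelihood logistic regression of the 8-year death indicator on
#' age, sex and comorbidity flags. BMI and any obesity flag are refused as
#' covariates by construction: the whole point of the baseline model is to
#' capture comorbidity-attributable risk so that BMI-attributable risk can
#' later be read from its residuals. Fitting goes through iteratively
#' reweighted least squares (`stats::glm`, convergence `|d logLik| < 1e-8`,
#' at most 100 iterations); binary covariates with fewer than `min_cases`
#' positive cases are dropped before fitting (they invite separation) and
#' recorded. An optional small ridge penalty on non-intercept terms is
#' available as a convergence rescue; when active it is reported in the
#' returned object.
#'
#' @param cohort A cohort table (see [generate_cohort()] /
#'   [validate_cohort_csv()]) with a 0/1 `death_8y` column.
#' @param covariates Character vector of cohort column names; may be empty
#'   for an intercept-only fit.
#' @param min_cases Minimum positive-case count for a binary covariate to
#'   enter the fit (default 5).
#' @param ridge Non-negative ridge penalty on non-intercept coefficients
#'   (default 0 = plain MLE).
#' @return An object of class `risk_model`: covariate list, `intercept`,
#'   named `coefficients`, `standard_errors` and `p_values` (Wald),
#'   `log_likelihood`, `converged`, `n_iterations`, `dropped_covariates`
#'   (data frame of name/reason), `n`, `ridge`, `warnings`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 2000, seed = 1))
#' m <- fit_logistic(cohort, c("age", "male", "diabetes_mellitus"))
#' m$coefficients
fit_logistic <- function(cohort, covariates, min_cases = 5, ridge = 0) {
  covariates <- as.character(covariates)
  forbidden <- intersect(tolower(covariates), c("bmi", "obesity"))
  if (length(forbidden))
    stop("covariates must exclude BMI and the obesity flag; found: ",
         paste(forbidden, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"death_8y" %in% names(cohort))
    stop("cohort lacks outcome column 'death_8y'", call. = FALSE)
  y <- cohort$death_8y
  if (length(unique(y)) < 2L)
    stop("outcome 'death_8y' has a single class; model is unfittable",
         call. = FALSE)

  dropped <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- covariates
  for (nm in covariates) {
    x <- cohort[[nm]]
    if (all(x %in% c(0, 1)) && sum(x == 1) < min_cases) {
      dropped <- rbind(dropped, data.frame(
        name = nm,
        reason = sprintf("fewer than %d positive cases (%d)",
                         min_cases, sum(x == 1)),
        stringsAsFactors = FALSE))
      keep <- setdiff(keep, nm)
    }
  }

  if (ridge > 0) {
    X <- cbind(`(Intercept)` = rep(1, length(y)),
               as.matrix(as.data.frame(cohort)[, keep, drop = FALSE]))
    storage.mode(X) <- "double"
    fit <- ridge_irls(X, y, ridge)
  } else {
    df <- data.frame(.y = y)
    for (nm in keep) df[[nm]] <- cohort[[nm]]
    fml <- if (length(keep))
      stats::reformulate(sprintf("`%s`", keep), response = ".y")
    else
      stats::as.formula(".y ~ 1")
    g <- glm(fml, family = binomial(), data = df,
             control = glm.control(epsilon = 1e-8, maxit = 100))
    sm <- summary(g)$coefficients
    cn <- gsub("`", "", rownames(sm))
    fit <- list(coef = setNames(sm[, 1], cn), se = setNames(sm[, 2], cn),
                p = setNames(sm[, 4], cn),
                loglik = as.numeric(logLik(g)),
                converged = g$converged, iter = g$iter)
  }

  warns <- character()
  big <- names(fit$coef)[abs(fit$coef) > 15 & names(fit$coef) != "(Intercept)"]
  if (length(big)) {
    warns <- sprintf("possible quasi-separation: |coefficient| > 15 for %s",
                     paste(big, collapse = ", "))
    warning(warns, call. = FALSE)
  }

  model <- structure(list(
    covariates = keep,
    intercept = unname(fit$coef["(Intercept)"]),
    coefficients = fit$coef[keep],
    standard_errors = fit$se[c("(Intercept)", keep)],
    p_values = fit$p[c("(Intercept)", keep)],
    log_likelihood = fit$loglik,
    converged = fit$converged,
    n_iterations = fit$iter,
    dropped_covariates = dropped,
    n = length(y),
    ridge = ridge,
    warnings = warns
  ), class = "risk_model")
  model$fingerprint <- model_fingerprint(model)
  model
}

# Penalized IRLS used only when a ridge rescue is requested: penalty
# ridge * sum(beta_j^2) over non-intercept terms; SEs from the inverse
# penalized Hessian.
ridge_irls <- function(X, y, ridge, epsilon = 1e-8, maxit = 100) {
  p <- ncol(X)
  D <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + D
    score <- crossprod(X, y - mu) - D %*% beta
    step <- solve(H, score)
    # step-halving on the penalized log-likelihood
    for (half in 0:20) {
      bnew <- beta + step / 2^half
      etan <- drop(X %*% bnew)
      ll <- sum(y * etan - log1p(exp(etan))) - 0.5 * sum(diag(D) * bnew^2)
      if (is.finite(ll) && ll >= ll_old - 1e-12) break
    }
    beta <- bnew
    if (abs(ll - ll_old) < epsilon) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  H <- crossprod(X, X * pmax(mu * (1 - mu), 1e-10)) + D
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se,
       p = setNames(2 * pnorm(-abs(z)), colnames(X)),
       loglik = sum(y * eta - log1p(exp(eta))),
       converged = converged, iter = it)
}

#' Backwards elimination on Wald p-values
#'
#' Starting from the full covariate list, repeatedly refits the logistic
#' model and removes the single covariate with the largest Wald p-value
#' exceeding `alpha`, until every remaining covariate is significant at
#' `alpha`. Elimination looks only at p-values, never at coefficient sign
#' (a collinearity-flipped but significant covariate is retained). The
#' removal order is recorded in `dropped_covariates`.
#'
#' @inheritParams fit_logistic
#' @param alpha Wald significance threshold in (0, 1\]; default 0.05.
#'   `alpha = 1` disables elimination.
#' @return A `risk_model` (see [fit_logistic()]) for the final covariate
#'   set; if every covariate is eliminated, an intercept-only model is
#'   returned with a warning.
#' @export
backwards_eliminate <- function(cohort, covariates, alpha = 0.05,
                                min_cases = 5, ridge = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  current <- as.character(covariates)
  eliminated <- data.frame(name = character(), reason = character(),
                           stringsAsFactors = FALSE)
  repeat {
    model <- fit_logistic(cohort, current, min_cases = min_cases,
                          ridge = ridge)
    current <- model$covariates  # rare flags may have been dropped pre-fit
    if (!length(current)) break
    pv <- model$p_values[current]
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    nm <- current[worst]
    eliminated <- rbind(eliminated, data.frame(
      name = nm,
      reason = sprintf("eliminated: Wald p = %.4g > alpha = %g",
                       pv[worst], alpha),
      stringsAsFactors = FALSE))
    current <- setdiff(current, nm)
    if (!length(current)) {
      warning("all covariates eliminated; returning intercept-only model",
              call. = FALSE)
      model <- fit_logistic(cohort, character(), min_cases = min_cases,
                            ridge = ridge)
      break
    }
  }
  model$dropped_covariates <- rbind(model$dropped_covariates, eliminated)
  model$fingerprint <- model_fingerprint(model)
  model
}

#' Predict per-subject baseline mortality risk
#'
#' Evaluates `plogis(intercept + sum(coef_j * x_j))` for every cohort row.
#' Probabilities are kept strictly inside (0, 1).
#'
#' @param model A `risk_model`.
#' @param cohort A cohort table containing every model covariate.
#' @return Numeric vector of probabilities, one per row, with attribute
#'   `fingerprint` identifying the generating model.
#' @export
predict_risk <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"))
  missing_cols <- setdiff(model$covariates, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks model covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  eta <- rep(model$intercept, nrow(cohort))
  for (nm in model$covariates)
    eta <- eta + model$coefficients[[nm]] * cohort[[nm]]
  p <- plogis(eta)
  eps <- .Machine$double.eps
  p <- pmin(pmax(p, eps), 1 - eps)
  attr(p, "fingerprint") <- model$fingerprint
  p
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the proportion of (case, control) pairs in
#' which the case has the higher predicted risk, ties counting one half.
#'
#' @param risks Numeric vector of predicted risks.
#' @param outcomes 0/1 outcome vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(risks, outcomes) {
  if (length(risks) != length(outcomes))
    stop("risks and outcomes must have equal length", call. = FALSE)
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1)))
    stop("outcomes must be 0/1", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  r <- rank(risks, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
model_fingerprint <- function(model) {
  txt <- paste(c(sprintf("%.17g", model$intercept),
                 sprintf("%s=%.17g", model$covariates,
                         model$coefficients[model$covariates])),
               collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Baseline mortality risk model (logistic, n = %d)\n", x$n))
  cat(sprintf("  converged: %s in %d IRLS iterations; logLik = %.3f%s\n",
              x$converged, x$n_iterations, x$log_likelihood,
              if (x$ridge > 0) sprintf(" (ridge = %g)", x$ridge) else ""))
  tab <- data.frame(coefficient = c(x$intercept,
                                    unname(x$coefficients[x$covariates])),
                    se = unname(x$standard_errors),
                    p = unname(x$p_values),
                    row.names = c("(Intercept)", x$covariates))
  print(round(tab, 4))
  if (nrow(x$dropped_covariates))
    cat("Dropped:", paste(sprintf("%s (%s)", x$dropped_covariates$name,
                                  x$dropped_covariates$reason),
                          collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a fitted risk model to JSON
#'
#' Coefficients, standard errors, p-values and convergence metadata are
#' written at full precision so that [read_model_json()] round-trips the
#' model bit-exactly.
#'
#' @param model A `risk_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(
    covariates = model$covariates,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    standard_errors = as.list(model$standard_errors),
    p_values = as.list(model$p_values),
    log_likelihood = model$log_likelihood,
    converged = model$converged,
    n_iterations = model$n_iterations,
    dropped_covariates = model$dropped_covariates,
    n = model$n,
    ridge = model$ridge,
    fingerprint = model$fingerprint
  )
  # digits = I(17): 17 significant digits, enough for a bit-exact
  # double-precision round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' Read a risk model written by [write_model_json()]
#'
#' @param path JSON file path.
#' @return A `risk_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dropped <- obj$dropped_covariates
  if (is.null(dropped) || length(dropped) == 0L)
    dropped <- data.frame(name = character(), reason = character(),
                          stringsAsFactors = FALSE)
  model <- structure(list(
    covariates = as.character(obj$covariates),
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    standard_errors = unlist(obj$standard_errors),
    p_values = unlist(obj$p_values),
    log_likelihood = obj$log_likelihood,
    converged = obj$converged,
    n_iterations = obj$n_iterations,
    dropped_covariates = dropped,
    n = obj$n,
    ridge = obj$ridge,
    warnings = character(),
    fingerprint = obj$fingerprint
  ), class = "risk_model")
  model
}
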