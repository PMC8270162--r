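# Independent oracles and fixture builders shared across test files.

# Brute-force Nadaraya-Watson weighted mean at a single point: an explicit
# subject-by-subject loop, independent of the package's vectorized path.
nw_oracle <- function(x, y, point, h) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    w <- exp(-0.5 * ((x[i] - point) / h)^2)
    num <- num + w * y[i]
    den <- den + w
  }
  if (den > 0) num / den else NA_real_
}

# Brute-force AUC: exhaustive enumeration of case-control pairs,
# ties counting one half.
auc_oracle <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  controls <- risks[outcomes == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Deterministic two-arm cohort: n0 subjects with x = 0 (k0 deaths) and n1
# with x = 1 (k1 deaths). Exact counts, so the logistic MLE has the
# closed-form 2x2 solution.
two_arm_cohort <- function(n0, k0, n1, k1) {
  df <- data.frame(
    subject_id = seq_len(n0 + n1),
    age = 50, male = 0L,
    x = rep(c(0L, 1L), c(n0, n1)),
    bmi = 25,
    death_8y = c(rep(c(1L, 0L), c(k0, n0 - k0)),
                 rep(c(1L, 0L), c(k1, n1 - k1))))
  attr(df, "comorbidities") <- "x"
  class(df) <- c("cohort_table", "data.frame")
  df
}

# Cohort with prescribed (n, deaths) per BMI category, subjects placed at
# the category midpoint (finite categories clamped to [13, 50]).
category_count_cohort <- function(n, deaths, mids) {
  df <- data.frame(
    subject_id = seq_len(sum(n)),
    age = 50, male = 0L,
    bmi = rep(mids, n),
    death_8y = unlist(mapply(function(nn, dd) rep(c(1L, 0L), c(dd, nn - dd)),
                             n, deaths, SIMPLIFY = FALSE)))
  attr(df, "comorbidities") <- character(0)
  class(df) <- c("cohort_table", "data.frame")
  df
}

# Small default-mechanism cohort cached per test run (used by several
# files; generation is ~0.2 s).
small_default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(synthetic_config(n_subjects = 20000,
                                                 seed = 404))
    cache
  }
})
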