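test_that("logistic MLE matches closed forms on deterministic counts", {
  # 2x2 design: coefficient is the log odds ratio, intercept the baseline
  # log odds
  coh <- two_arm_cohort(n0 = 4000, k0 = 800, n1 = 4000, k1 = 2400)
  m <- fit_logistic(coh, "x")
  expect_true(m$converged)
  expect_equal(unname(m$coefficients["x"]),
               log((0.6 / 0.4) / (0.2 / 0.8)), tolerance = 1e-6)
  expect_equal(unname(m$coefficients["x"]), log(6), tolerance = 1e-6)
  expect_equal(m$intercept, log(0.2 / 0.8), tolerance = 1e-6)

  # intercept-only fit: logit of the death proportion
  m0 <- fit_logistic(coh, character(0))
  expect_equal(m0$intercept, qlogis(3200 / 8000), tolerance = 1e-8)

  # score equation: mean residual over the fitting cohort is zero
  for (model in list(m, m0)) {
    p <- predict_risk(model, coh)
    expect_lt(abs(mean(coh$death_8y - p)), 1e-6)
  }
})

test_that("fit refuses BMI/obesity covariates and single-class outcomes", {
  coh <- two_arm_cohort(100, 20, 100, 60)
  expect_error(fit_logistic(coh, c("x", "bmi")), "bmi")
  coh$obesity <- 0L
  expect_error(fit_logistic(coh, "obesity"), "obesity")
  expect_error(fit_logistic(coh, "nope"), "nope")
  coh$death_8y <- 0L
  expect_error(fit_logistic(coh, "x"), "single class")
})

test_that("rare binary covariates are dropped pre-fit and recorded", {
  coh <- two_arm_cohort(500, 100, 500, 300)
  coh$rare <- c(rep(1L, 3), rep(0L, 997))
  m <- fit_logistic(coh, c("x", "rare"))
  expect_identical(m$covariates, "x")
  expect_equal(m$dropped_covariates$name, "rare")
  expect_match(m$dropped_covariates$reason, "fewer than 5")
  expect_false("rare" %in% names(m$coefficients))
  # configurable guard; the 3 rare carriers are all deaths, so letting the
  # flag in must trigger the quasi-separation warning yet still return a fit
  expect_warning(m2 <- fit_logistic(coh, c("x", "rare"), min_cases = 2),
                 "quasi-separation")
  expect_true("rare" %in% m2$covariates)
  expect_match(m2$warnings, "rare")
})

test_that("predict_risk evaluates the published coefficient examples", {
  ex <- elixhauser_defaults()
  model <- structure(list(
    covariates = c("age", "male", ex$name),
    intercept = -8.112,
    coefficients = c(age = 0.082, male = 0.231,
                     setNames(ex$coefficient, ex$name)),
    fingerprint = "frozen"), class = "risk_model")
  subj <- data.frame(subject_id = 1:2, age = c(50, 80), male = c(1L, 0L),
                     bmi = 25, death_8y = 0L)
  for (nm in ex$name) subj[[nm]] <- 0L
  subj[2, c("congestive_heart_disease", "coronary_artery_disease",
            "chronic_kidney_disease")] <- 1L
  p <- predict_risk(model, subj)
  # logits from the printed coefficients: -3.781 and 0.262
  expect_equal(unname(p[1]), plogis(-8.112 + 0.082 * 50 + 0.231))
  expect_equal(unname(p[1]), 0.02231, tolerance = 1e-3)
  expect_equal(unname(p[2]),
               plogis(-8.112 + 0.082 * 80 + 0.860 + 0.342 + 0.612))
  expect_equal(unname(p[2]), 0.5651, tolerance = 1e-3)
  expect_true(all(p > 0 & p < 1))
  expect_identical(attr(p, "fingerprint"), "frozen")
  expect_error(predict_risk(model, subj[, -3]), "male")
})

test_that("predict_risk is monotone in positively weighted covariates", {
  coh <- small_default_cohort()
  m <- fit_logistic(coh, c("age", "male", "diabetes_mellitus",
                           "congestive_heart_disease"))
  base <- data.frame(subject_id = 1, age = 60, male = 0L,
                     diabetes_mellitus = 0L, congestive_heart_disease = 0L)
  for (nm in names(m$coefficients)) {
    lo <- base; hi <- base
    hi[[nm]] <- base[[nm]] + 1
    d <- predict_risk(m, hi) - predict_risk(m, lo)
    expect_true(sign(d) == sign(m$coefficients[[nm]]), label = nm)
  }
})

test_that("AUC equals exhaustive pair counting and known values", {
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # both case-control pairs concordant (0.5 > 0.3, 0.4 > 0.3)
  expect_equal(compute_auc(c(0.3, 0.5, 0.4), c(0, 1, 1)),
               auc_oracle(c(0.3, 0.5, 0.4), c(0, 1, 1)))
  expect_equal(compute_auc(c(0.3, 0.5, 0.4), c(0, 1, 1)), 1.0)
  # 3 of 4 pairs concordant
  expect_equal(compute_auc(c(0.3, 0.5, 0.4, 0.45), c(0, 1, 1, 0)), 0.75)
  expect_equal(auc_oracle(c(0.3, 0.5, 0.4, 0.45), c(0, 1, 1, 0)), 0.75)
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "single class")

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    r <- round(runif(n), 2)  # rounded so ties actually occur
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(compute_auc(r, y), auc_oracle(r, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  r <- runif(300); y <- rbinom(300, 1, plogis(3 * r - 2))
  expect_equal(compute_auc(r, y),
               as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("backwards elimination removes noise and keeps signal", {
  kept_real <- 0; killed_noise <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 20000
    x_real <- rbinom(n, 1, 0.3)
    x_noise <- rbinom(n, 1, 0.3)
    y <- rbinom(n, 1, plogis(-2 + 1.0 * x_real))
    coh <- data.frame(subject_id = 1:n, age = 50, male = 0L,
                      x_real = x_real, x_noise = x_noise,
                      bmi = 25, death_8y = y)
    m <- backwards_eliminate(coh, c("x_real", "x_noise"), alpha = 0.05)
    kept_real <- kept_real + ("x_real" %in% m$covariates)
    killed_noise <- killed_noise + !("x_noise" %in% m$covariates)
    if (!("x_noise" %in% m$covariates))
      expect_match(
        m$dropped_covariates$reason[m$dropped_covariates$name == "x_noise"],
        "Wald p")
  }
  expect_gte(kept_real, 19)
  expect_gte(killed_noise, 19)
})

test_that("elimination boundary cases: no-op, alpha = 1, all removed", {
  coh <- two_arm_cohort(4000, 800, 4000, 2400)
  # already significant: identical to the plain fit
  full <- fit_logistic(coh, "x")
  kept <- backwards_eliminate(coh, "x", alpha = 0.05)
  expect_equal(kept$coefficients, full$coefficients)
  expect_equal(kept$p_values, full$p_values)

  # alpha = 1 never removes anything
  set.seed(12)
  coh$junk <- rbinom(nrow(coh), 1, 0.5)
  m1 <- backwards_eliminate(coh, c("x", "junk"), alpha = 1.0)
  expect_setequal(m1$covariates, c("x", "junk"))

  # pure-noise covariate set collapses to intercept-only with a warning
  set.seed(13)
  coh2 <- data.frame(subject_id = 1:500, age = 50, male = 0L,
                     z = rbinom(500, 1, 0.5), bmi = 25,
                     death_8y = rbinom(500, 1, 0.2))
  expect_warning(m0 <- backwards_eliminate(coh2, "z", alpha = 1e-6),
                 "intercept-only")
  expect_length(m0$covariates, 0)
})

test_that("fitted models serialize to JSON and round-trip bit-exactly", {
  coh <- small_default_cohort()
  m <- fit_logistic(coh, c("age", "male", "diabetes_mellitus", "stroke"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(m2$intercept, m$intercept)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$standard_errors, m$standard_errors)
  expect_identical(m2$p_values, m$p_values)
  expect_identical(m2$fingerprint, m$fingerprint)
  expect_identical(predict_risk(m2, coh), predict_risk(m, coh))
})

test_that("coefficients recover generating values on a synthetic cohort", {
  # single-seed spot check (the 20-seed version lives with the acceptance
  # checks); congestive heart disease generates at 0.860
  cfg <- synthetic_config(
    n_subjects = 50000, seed = 2024,
    bmi_effect = list(hinge_low_knot = 20, hinge_low_slope = 0,
                      hinge_high_knot = 40, hinge_high_slope = 0))
  coh <- generate_cohort(cfg)
  m <- fit_logistic(coh, c("age", "male", comorbidity_names(coh)))
  truth <- c(cfg$true_coefficients,
             `(Intercept)` = cfg$true_intercept)
  est <- c(m$coefficients, `(Intercept)` = m$intercept)
  for (nm in c("(Intercept)", "age", "male", "congestive_heart_disease",
               "diabetes_mellitus", "hyperlipidemia")) {
    se <- m$standard_errors[[if (nm == "(Intercept)") "(Intercept)" else nm]]
    expect_lt(abs(est[[nm]] - truth[[nm]]), 3 * se, label = nm)
  }
})
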