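test_that("BMI categories use [lo, hi) intervals over the default breaks", {
  s <- bmi_category_scheme()
  expect_equal(s$labels, c("<15", "15-<20", "20-<25", "25-<30", "30-<35",
                           "35-<40", "40-<45", ">=45"))
  f <- bmi_categorize(c(14.99, 15, 19.99, 20, 44.99, 45, 60), s)
  expect_equal(as.character(f),
               c("<15", "15-<20", "15-<20", "20-<25", "40-<45", ">=45",
                 ">=45"))
  expect_error(bmi_category_scheme(c(20, 15)), "increasing")
})

test_that("category rate table counts exactly and flags empty categories", {
  mids <- c(13, 17.5, 22.5, 27.5, 32.5, 37.5, 42.5, 50)
  n <- c(22, 40, 100, 80, 0, 10, 5, 30)
  deaths <- c(8, 6, 10, 9, 0, 0, 5, 3)
  coh <- category_count_cohort(n[n > 0], deaths[n > 0], mids[n > 0])
  tab <- categorical_rate_table(coh)
  expect_equal(tab$n, n)
  expect_equal(tab$deaths, deaths)
  expect_equal(tab$rate, ifelse(n > 0, deaths / n, NA_real_))
  # published example cells: 8/22 -> 0.364 and 0-death category -> 0.000
  fmt <- format_rate_table(tab)
  expect_equal(fmt$rate[1], "0.364")
  expect_equal(fmt$rate[6], "0.000")
  expect_equal(fmt$rate[5], "")  # empty category is never 0/0 = 0
  # rate * n reproduces deaths exactly at full precision
  expect_equal(tab$rate[n > 0] * tab$n[n > 0], as.numeric(deaths[n > 0]))
})

test_that("entire-cohort row equals the sum of the per-group rows", {
  coh <- small_default_cohort()
  m <- fit_logistic(coh, c("age", "male", comorbidity_names(coh)))
  g <- assign_risk_groups(predict_risk(m, coh))
  tab <- categorical_rate_table(coh, g)
  whole <- tab[tab$group == "EntireCohort", ]
  by_grp <- tab[tab$group != "EntireCohort", ]
  for (cat in levels(tab$category)) {
    expect_equal(sum(by_grp$n[by_grp$category == cat]),
                 whole$n[whole$category == cat])
    expect_equal(sum(by_grp$deaths[by_grp$category == cat]),
                 whole$deaths[whole$category == cat])
  }
  expect_equal(sum(whole$n), nrow(coh))
  expect_equal(sum(whole$deaths), sum(coh$death_8y))
})

test_that("kernel curve reduces to constants and respects locality", {
  # constant outcomes: weighted mean of ones is one everywhere defined
  cv <- kernel_rate_curve(runif(50, 20, 30), rep(1, 50))
  expect_true(all(cv$estimate[cv$defined] == 1))

  # two distant clusters: local value at each, symmetric midpoint at 0.5,
  # and the midpoint is flagged undefined (negligible kernel mass)
  bmi <- c(rep(25, 100), rep(45, 100))
  y <- c(rep(1, 100), rep(0, 100))
  cv <- kernel_rate_curve(bmi, y, grid = c(25, 35, 45), bandwidth = 0.5)
  expect_gte(cv$estimate[1], 0.999)
  expect_equal(cv$estimate[2], 0.5)
  expect_false(cv$defined[2])
  expect_lte(cv$estimate[3], 0.001)
  expect_true(cv$defined[1] && cv$defined[3])

  expect_error(kernel_rate_curve(numeric(0), numeric(0)), "empty")
  expect_error(kernel_rate_curve(25, 1, bandwidth = 0), "bandwidth")
})

test_that("kernel curve matches the brute-force loop oracle", {
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    bmi <- runif(n, 14, 56)
    y <- rbinom(n, 1, 0.3)
    h <- runif(1, 0.3, 2)
    grid <- bmi_grid()
    cv <- kernel_rate_curve(bmi, y, grid = grid, bandwidth = h)
    for (k in sample(length(grid), 12))
      expect_equal(cv$estimate[k], nw_oracle(bmi, y, grid[k], h),
                   tolerance = 1e-12)
  }
})

test_that("kernel curve is invariant to order and subject duplication", {
  set.seed(14)
  bmi <- runif(80, 16, 50); y <- rbinom(80, 1, 0.4)
  cv <- kernel_rate_curve(bmi, y)
  perm <- sample(80)
  expect_equal(kernel_rate_curve(bmi[perm], y[perm])$estimate, cv$estimate)
  dup <- kernel_rate_curve(rep(bmi, 2), rep(y, 2))
  expect_equal(dup$estimate, cv$estimate)
  expect_equal(dup$mass, 2 * cv$mass)
})

test_that("small-bandwidth limit recovers co-located outcome means", {
  bmi <- c(30, 30, 30, 33, 29)  # nothing else within 10h of grid point 30
  y <- c(1, 0, 1, 1, 0)
  cv <- kernel_rate_curve(bmi, y, grid = 30, bandwidth = 0.05)
  expect_true(cv$defined)
  expect_equal(cv$estimate, 2 / 3, tolerance = 1e-9)
})

test_that("bootstrap bands are seeded, ordered and collapse on constants", {
  set.seed(3)
  bmi <- runif(400, 20, 35)
  y <- rbinom(400, 1, 0.25)
  b1 <- bootstrap_band(kernel_rate_curve, bmi, y, n_boot = 50, seed = 99)
  b2 <- bootstrap_band(kernel_rate_curve, bmi, y, n_boot = 50, seed = 99)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  d <- b1[b1$defined, ]
  ok <- !(b1$grid[b1$defined] %in% attr(b1, "outside_range"))
  expect_true(all(d$ci_lower[ok] <= d$estimate[ok] + 1e-12))
  expect_true(all(d$estimate[ok] <= d$ci_upper[ok] + 1e-12))
  expect_true(all(d$estimate >= 0 & d$estimate <= 1))

  # degenerate outcomes: the band collapses to the constant
  bc <- bootstrap_band(kernel_rate_curve, bmi, rep(1, 400), n_boot = 20,
                       seed = 1)
  dd <- bc[bc$defined, ]
  expect_true(all(dd$ci_lower == 1 & dd$ci_upper == 1 & dd$estimate == 1))

  expect_error(bootstrap_band(kernel_rate_curve, 25, 1, n_boot = 10),
               "fewer than 2")
  expect_error(bootstrap_band(kernel_rate_curve, bmi, y, n_boot = 1),
               "n_boot")
})

test_that("per-group curves resample within their own stratum", {
  coh <- generate_cohort(synthetic_config(n_subjects = 4000, seed = 5))
  m <- fit_logistic(coh, c("age", "male"))
  g <- assign_risk_groups(predict_risk(m, coh))
  cv <- curves_by_group(coh, g, n_boot = 20, seed = 7)
  expect_named(cv, c("EntireCohort", levels(g$group)))
  # the Low stratum curve must be reproducible from its own subjects alone
  idx <- which(g$group == "Low")
  solo <- bootstrap_band(kernel_rate_curve, coh$bmi[idx], coh$death_8y[idx],
                         n_boot = 20, seed = 7 + 2)
  expect_identical(as.data.frame(cv$Low), as.data.frame(solo))
})
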