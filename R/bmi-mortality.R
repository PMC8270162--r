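#' BMI category scheme
#'
#' Five-unit BMI categories from <15 to >=45 kg/m^2, the study's deliberate
#' alternative to the WHO/NIH 18.5-based cut-offs. Intervals are half-open
#' `[lo, hi)`, so the "15-<20" category contains BMI 15 but not 20.
#'
#' @param breakpoints Strictly increasing numeric vector of interior
#'   breakpoints (kg/m^2); `-Inf`/`Inf` are added automatically if absent.
#' @return Object of class `bmi_scheme`: `breaks` (including infinities)
#'   and `labels` such as `"<15"`, `"15-<20"`, `">=45"`.
#' @export
#' @examples
#' bmi_category_scheme()$labels
bmi_category_scheme <- function(breakpoints = c(15, 20, 25, 30, 35, 40, 45)) {
  b <- as.numeric(breakpoints)
  b <- b[is.finite(b)]
  if (length(b) < 1L || is.unsorted(b, strictly = TRUE))
    stop("breakpoints must be strictly increasing", call. = FALSE)
  breaks <- c(-Inf, b, Inf)
  fmt <- function(x) formatC(x, format = "g")
  labels <- c(sprintf("<%s", fmt(b[1L])),
              if (length(b) > 1L)
                sprintf("%s-<%s", fmt(b[-length(b)]), fmt(b[-1L])),
              sprintf(">=%s", fmt(b[length(b)])))
  structure(list(breaks = breaks, labels = labels), class = "bmi_scheme")
}

#' Categorize BMI values
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @param scheme A [bmi_category_scheme()].
#' @return Factor of category labels, `[lo, hi)` convention.
#' @export
bmi_categorize <- function(bmi, scheme = bmi_category_scheme()) {
  stopifnot(inherits(scheme, "bmi_scheme"))
  cut(bmi, breaks = scheme$breaks, labels = scheme$labels, right = FALSE)
}

#' Raw mortality rates by BMI category and risk group
#'
#' Exact integer counting of subjects and deaths per BMI category, for the
#' entire cohort and (when `groups` is supplied) each risk group. The rate
#' is `deaths / n` at full precision; an empty category keeps `rate = NA`
#' rather than 0. Rounding to 3 decimals is applied only by
#' [format_rate_table()] on output.
#'
#' @param cohort Cohort table with `bmi` and `death_8y` columns.
#' @param groups Optional [assign_risk_groups()] result aligned with
#'   `cohort` rows.
#' @param scheme A [bmi_category_scheme()].
#' @return Data frame of class `rate_table` with columns `group`,
#'   `category`, `n`, `deaths`, `rate`; `group` includes `"EntireCohort"`.
#' @export
categorical_rate_table <- function(cohort, groups = NULL,
                                   scheme = bmi_category_scheme()) {
  if (!all(c("bmi", "death_8y") %in% names(cohort)))
    stop("cohort must have 'bmi' and 'death_8y' columns", call. = FALSE)
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "risk_groups"))
    if (length(groups$group) != nrow(cohort))
      stop("groups are not aligned with the cohort", call. = FALSE)
  }
  cat_f <- bmi_categorize(cohort$bmi, scheme)
  one_stratum <- function(idx, label) {
    n <- tabulate(cat_f[idx], nbins = nlevels(cat_f))
    deaths <- vapply(seq_len(nlevels(cat_f)), function(k)
      sum(cohort$death_8y[idx][as.integer(cat_f[idx]) == k]), numeric(1))
    data.frame(group = label, category = levels(cat_f), n = n,
               deaths = as.integer(deaths),
               rate = ifelse(n > 0, deaths / n, NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- one_stratum(seq_len(nrow(cohort)), "EntireCohort")
  if (!is.null(groups)) {
    for (g in levels(groups$group))
      out <- rbind(out, one_stratum(which(groups$group == g), g))
  }
  out$category <- factor(out$category, levels = levels(cat_f))
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Format a rate table for display (rates at 3 decimals)
#'
#' @param tab A [categorical_rate_table()] result.
#' @return Data frame with `rate` formatted as a 3-decimal string
#'   (`""` for empty categories).
#' @export
format_rate_table <- function(tab) {
  out <- as.data.frame(tab)
  out$rate <- ifelse(is.na(out$rate), "", sprintf("%.3f", out$rate))
  out
}

# Nadaraya-Watson core. Gaussian kernel in unit-height form
# K(u) = exp(-u^2 / 2), so `mass` at a grid point is the equivalent number
# of subjects co-located there (one subject exactly at the point adds 1).
nw_smooth <- function(x, y, grid, bandwidth) {
  est <- mass <- numeric(length(grid))
  for (k in seq_along(grid)) {
    w <- exp(-0.5 * ((x - grid[k]) / bandwidth)^2)
    sw <- sum(w)
    mass[k] <- sw
    est[k] <- if (sw > 0) sum(w * y) / sw else NA_real_
  }
  list(estimate = est, mass = mass)
}

#' Kernel-smoothed mortality rate over a BMI grid
#'
#' Nadaraya-Watson estimate of the outcome mean at each grid point, with a
#' Gaussian kernel: `m(b) = sum(K((bmi_i - b)/h) * y_i) / sum(K(...))`. The
#' kernel is used in unit-height form so the reported `mass` (sum of
#' weights) reads as the equivalent number of co-located subjects; grid
#' points with `mass < mass_threshold` are flagged `defined = FALSE`
#' rather than silently extrapolated (the numeric estimate is still
#' reported where it is computable).
#'
#' @param bmi Numeric BMI values (kg/m^2), aligned with `outcomes`.
#' @param outcomes Numeric outcomes (0/1 deaths, or residuals).
#' @param grid Evaluation grid (kg/m^2); default 15 to 55 by 0.5.
#' @param bandwidth Kernel bandwidth h in kg/m^2; default 0.5.
#' @param mass_threshold Minimum weight mass for a grid point to count as
#'   defined; default 1 (one co-located subject).
#' @return Data frame: `grid`, `estimate`, `mass`, `defined`.
#' @export
#' @examples
#' kernel_rate_curve(c(24.9, 25.1, 30), c(1, 0, 1), grid = c(25, 30))
kernel_rate_curve <- function(bmi, outcomes, grid = bmi_grid(),
                              bandwidth = 0.5, mass_threshold = 1.0) {
  if (length(bmi) == 0L)
    stop("empty input: no subjects to smooth", call. = FALSE)
  if (length(bmi) != length(outcomes))
    stop("bmi and outcomes must have equal length", call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  s <- nw_smooth(bmi, outcomes, grid, bandwidth)
  defined <- s$mass >= mass_threshold
  if (!any(defined))
    warning("no grid point reaches the mass threshold", call. = FALSE)
  data.frame(grid = grid, estimate = s$estimate, mass = s$mass,
             defined = defined)
}

#' Default continuous BMI grid (15 to 55 kg/m^2 by 0.5)
#'
#' @param from,to,by Grid bounds and step in kg/m^2.
#' @return Numeric vector.
#' @export
bmi_grid <- function(from = 15, to = 55, by = 0.5) seq(from, to, by = by)

#' Percentile bootstrap band for a smoothed curve
#'
#' Resamples subjects with replacement within the stratum being curved,
#' re-evaluates the kernel estimator on each resample, and reports the
#' empirical 2.5th/97.5th percentile band per grid point. The point
#' estimate is the full-sample value; the bootstrap mean is stored
#' alongside for plotting. Seeded and fully reproducible.
#'
#' @param estimator Curve procedure with signature
#'   `(bmi, outcomes, grid, bandwidth, mass_threshold)` returning a data
#'   frame with an `estimate` column; default [kernel_rate_curve()].
#' @param bmi,outcomes Aligned subject vectors for one stratum.
#' @param grid,bandwidth,mass_threshold Passed to the estimator.
#' @param n_boot Number of bootstrap resamples (>= 2); default 200.
#' @param seed Integer seed for the resampling RNG.
#' @param conf Band coverage level; default 0.95.
#' @return Object of class `smoothed_curve`: a data frame with `grid`,
#'   `estimate`, `boot_mean`, `ci_lower`, `ci_upper`, `mass`, `defined`,
#'   plus attributes `bandwidth`, `n_boot`, `seed`, `outside_range`
#'   (grid points where the full-sample estimate falls outside the
#'   bootstrap draw range).
#' @export
bootstrap_band <- function(estimator = kernel_rate_curve, bmi, outcomes,
                           grid = bmi_grid(), bandwidth = 0.5,
                           n_boot = 200, seed = 1L, mass_threshold = 1.0,
                           conf = 0.95) {
  if (length(bmi) < 2L)
    stop("stratum has fewer than 2 subjects; cannot bootstrap",
         call. = FALSE)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  full <- estimator(bmi, outcomes, grid = grid, bandwidth = bandwidth,
                    mass_threshold = mass_threshold)
  n <- length(bmi)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- suppressWarnings(
      estimator(bmi[idx], outcomes[idx], grid = grid,
                bandwidth = bandwidth,
                mass_threshold = mass_threshold)$estimate)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE, type = 7)
  boot_mean <- colMeans(boot, na.rm = TRUE)
  rng <- apply(boot, 2, function(v)
    if (all(is.na(v))) c(NA_real_, NA_real_) else range(v, na.rm = TRUE))
  outside <- full$defined & !is.na(full$estimate) &
    (full$estimate < rng[1, ] | full$estimate > rng[2, ])
  out <- data.frame(grid = grid, estimate = full$estimate,
                    boot_mean = boot_mean,
                    ci_lower = ci[1, ], ci_upper = ci[2, ],
                    mass = full$mass, defined = full$defined)
  structure(out, bandwidth = bandwidth, n_boot = n_boot,
            seed = as.integer(seed),
            outside_range = grid[which(outside)],
            class = c("smoothed_curve", "data.frame"))
}

#' Smoothed rate or residual curves per risk group
#'
#' Convenience wrapper running [bootstrap_band()] for the entire cohort and
#' each risk group. Each stratum is resampled within itself, so each band
#' reflects only that stratum's sampling noise.
#'
#' @param cohort Cohort table.
#' @param groups Optional [assign_risk_groups()] result; when `NULL` only
#'   the entire-cohort curve is produced.
#' @param outcomes Numeric vector to smooth (deaths or residuals), aligned
#'   with `cohort`; default `cohort$death_8y`.
#' @param seed Base seed; stratum k uses `seed + k`.
#' @inheritParams bootstrap_band
#' @return Named list of `smoothed_curve` objects
#'   (`EntireCohort`, then one per group level).
#' @export
curves_by_group <- function(cohort, groups = NULL,
                            outcomes = cohort$death_8y,
                            grid = bmi_grid(), bandwidth = 0.5,
                            n_boot = 200, seed = 1L,
                            mass_threshold = 1.0) {
  strata <- list(EntireCohort = seq_len(nrow(cohort)))
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "risk_groups"))
    for (g in levels(groups$group)) strata[[g]] <- which(groups$group == g)
  }
  out <- list()
  for (k in seq_along(strata)) {
    idx <- strata[[k]]
    out[[names(strata)[k]]] <- bootstrap_band(
      kernel_rate_curve, cohort$bmi[idx], outcomes[idx], grid = grid,
      bandwidth = bandwidth, n_boot = n_boot,
      seed = as.integer(seed) + k, mass_threshold = mass_threshold)
  }
  out
}

#' Plot a smoothed curve with its bootstrap band
#'
#' Solid line: full-sample kernel estimate at defined grid points; open
#' circles: bootstrap means; dashed lines: the 95% percentile band. For
#' residual curves a zero reference line is drawn.
#'
#' @param x A `smoothed_curve`.
#' @param zero_line Draw a horizontal reference at 0 (use for residual
#'   curves).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.smoothed_curve <- function(x, zero_line = FALSE, ...) {
  d <- x[x$defined & !is.na(x$estimate), ]
  if (!nrow(d)) stop("no defined grid points to plot", call. = FALSE)
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- expression(BMI ~ (kg / m^2))
  if (is.null(args$ylab))
    args$ylab <- if (zero_line) "Excess 8-year mortality risk"
                 else "8-year mortality rate"
  if (is.null(args$ylim))
    args$ylim <- range(d$ci_lower, d$ci_upper, d$estimate, na.rm = TRUE)
  do.call(plot, c(list(d$grid, d$estimate, type = "l"), args))
  lines(d$grid, d$ci_lower, lty = 2)
  lines(d$grid, d$ci_upper, lty = 2)
  points(d$grid, d$boot_mean, pch = 1, cex = 0.6)
  if (zero_line) abline(h = 0, col = "grey40")
  invisible(x)
}
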