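#' Assign percentile-based mortality risk groups
#'
#' Partitions subjects into five baseline-risk strata by empirical
#' percentiles of predicted risk, cut at the 50th, 75th, 90th and 95th
#' percentiles by default: Low = bottom half, Medium = (50, 75\], MediumHigh
#' = (75, 90\], High = (90, 95\], VeryHigh = top 5%. Quantiles use the
#' linear-interpolation definition (`stats::quantile` type 7) and intervals
#' are half-open upward, so a subject whose risk equals a cut point falls in
#' the lower group. A constant risk vector yields all-Low with a warning.
#'
#' @param risks Non-empty numeric vector of predicted risks (one per
#'   subject, in subject order).
#' @param probs Increasing percentile cut points in (0, 1); default
#'   `c(0.50, 0.75, 0.90, 0.95)`.
#' @param labels Group labels, `length(probs) + 1` of them, low to high.
#' @return An object of class `risk_groups`: `group` (factor aligned with
#'   `risks`, levels in ascending risk order), `cut_points` (realized risk
#'   thresholds, named by percentile) and `group_sizes`.
#' @export
#' @examples
#' g <- assign_risk_groups((1:100) / 101)
#' g$group_sizes
assign_risk_groups <- function(risks,
                               probs = c(0.50, 0.75, 0.90, 0.95),
                               labels = c("Low", "Medium", "MediumHigh",
                                          "High", "VeryHigh")) {
  if (length(risks) == 0L || any(!is.finite(risks)))
    stop("risks must be a non-empty vector of finite values", call. = FALSE)
  if (is.unsorted(probs, strictly = TRUE) || any(probs <= 0 | probs >= 1))
    stop("probs must be strictly increasing and lie in (0, 1)",
         call. = FALSE)
  if (length(labels) != length(probs) + 1L)
    stop("need length(probs) + 1 labels", call. = FALSE)
  q <- quantile(risks, probs, type = 7, names = FALSE)
  if (diff(range(risks)) == 0) {
    warning("constant risk vector: every subject assigned to the lowest group",
            call. = FALSE)
    group <- factor(rep(labels[1L], length(risks)), levels = labels)
  } else {
    breaks <- c(-Inf, q, Inf)
    # collapse duplicated cut points: ties at a threshold go to the lower group
    keep <- !duplicated(breaks)
    group <- cut(risks, breaks = breaks[keep],
                 labels = labels[keep[-1L]], right = TRUE)
    group <- factor(as.character(group), levels = labels)
  }
  structure(list(group = group,
                 cut_points = setNames(q, sprintf("p%g", 100 * probs)),
                 group_sizes = table(group)),
            class = "risk_groups")
}

#' @export
print.risk_groups <- function(x, ...) {
  cat("Percentile risk groups\n")
  print(x$group_sizes)
  cat("Cut points (risk scale):\n")
  print(signif(x$cut_points, 4))
  invisible(x)
}
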