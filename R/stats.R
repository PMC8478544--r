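#' Method agreement: linear model plus Bland-Altman
#'
#' Given paired measurements from two methods, fits ordinary least squares
#' of method B on method A (A on the x-axis), and computes Bland-Altman
#' agreement statistics: the bias (mean difference B - A) and the limits of
#' agreement at `bias +/- multiplier * sd(differences)` (classic multiplier
#' 1.96).
#'
#' @param a,b Numeric vectors of paired measurements (method A is the
#'   reference / x-axis).
#' @param multiplier Limits-of-agreement multiplier.
#' @return An object of class `agreement`: `n`, `slope`, `intercept`,
#'   `r_squared`, `bias`, `loa_low`, `loa_high`, `outside_loa` (count of
#'   pairs beyond the limits), and `data` (a data frame with `a`, `b`,
#'   `mean`, `diff` for plotting).
#' @examples
#' a <- c(10, 12, 14, 16, 18)
#' agreement(a, a + 5)  # bias 5, zero-width limits
#' @export
agreement <- function(a, b, multiplier = 1.96) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b))
    am_stop("paired series must have equal length", "am_value_error")
  if (length(a) < 3L)
    am_stop("agreement needs at least 3 pairs", "am_value_error")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    am_stop("agreement needs finite values", "am_value_error")
  if (sd(a) == 0)
    am_stop("method A has zero variance: fit is degenerate",
            "am_degenerate_fit_error")
  fit <- lm(b ~ a)
  d <- b - a
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - multiplier * s
  loa_high <- bias + multiplier * s
  structure(list(
    n = length(a),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    bias = bias,
    loa_low = loa_low,
    loa_high = loa_high,
    outside_loa = sum(d < loa_low | d > loa_high),
    multiplier = multiplier,
    data = data.frame(a = a, b = b, mean = (a + b) / 2, diff = d)),
    class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("agreement (n = %d):\n", x$n))
  cat(sprintf("  OLS b ~ a: slope %.4g, intercept %.4g, r^2 %.4g\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  bias %.4g, limits of agreement [%.4g, %.4g], %d pair(s) outside\n",
              x$bias, x$loa_low, x$loa_high, x$outside_loa))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias and limits of agreement.
#'
#' @param x An [agreement()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement <- function(x, ...) {
  plot(x$data$mean, x$data$diff, xlab = "mean of methods",
       ylab = "difference (B - A)", ...)
  abline(h = x$bias, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Validate automatic per-slice metrics against manual measurements
#'
#' Manual per-slice measurements (typically repeated several times per
#' slice) are averaged per slice and metric, matched to the automatic
#' per-slice metrics by slice identifier, and compared with [agreement()]
#' per metric.
#'
#' @param per_slice Automatic per-slice metrics from [per_slice_metrics()]
#'   (or any data frame with a `slice` column and one column per metric).
#' @param manual Data frame of manual measurements with columns `slice`,
#'   `metric`, `value`; one row per repeat.
#' @param metrics Metric names to compare.
#' @return Named list of [agreement()] results, one per metric (manual is
#'   method A, automatic is method B).
#' @export
paired_pipeline_validation <- function(per_slice, manual,
                                       metrics = c("stenosis",
                                                   "lesion_length_fraction")) {
  if (!all(c("slice", "metric", "value") %in% names(manual)))
    am_stop("`manual` needs columns slice, metric, value", "am_value_error")
  out <- list()
  for (m in metrics) {
    man <- manual[manual$metric == m, , drop = FALSE]
    if (nrow(man) == 0L)
      am_stop(sprintf("no manual measurements for metric '%s'", m),
              "am_value_error")
    avg <- aggregate(value ~ slice, data = man, FUN = mean)
    if (!all(avg$slice %in% per_slice$slice))
      am_stop(sprintf(
        "manual slices missing from automatic metrics for '%s'", m),
        "am_value_error")
    auto <- per_slice[[m]][match(avg$slice, per_slice$slice)]
    out[[m]] <- agreement(avg$value, auto)
  }
  out
}

#' One-way group comparison of specimen outcomes
#'
#' Thin wrapper around [stats::aov()] for comparing an outcome across
#' groups (e.g. genotype at one time point) in a table of per-specimen
#' reports.
#'
#' @param values Numeric outcome per specimen.
#' @param group Group factor per specimen.
#' @return List with `f`, `df`, `p_value`, and the fitted `aov` object.
#' @export
group_compare <- function(values, group) {
  fit <- aov(values ~ factor(group))
  s <- summary(fit)[[1]]
  list(f = s$`F value`[1], df = s$Df, p_value = s$`Pr(>F)`[1], fit = fit)
}
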