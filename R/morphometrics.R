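#' Percent change of a linear measurement during decay
#'
#' By default the change is `100 * (value_at_day - value_at_death) /
#' value_at_death`, so post-mortem elongation and bloating are positive —
#' consistent with how decay-induced changes of 10-30% are usually quoted.
#' Set `legacy_sign = TRUE` for the opposite convention
#' `100 * (original - decayed) / original`, in which shrinkage is positive.
#'
#' @param value_at_death original dimension (> 0); vectorized.
#' @param value_at_day dimension at the sampling day (> 0).
#' @param legacy_sign flip the sign convention.
#' @return Percent change (dimensionless, > -100 under the default
#'   convention).
#' @export
percent_change <- function(value_at_death, value_at_day,
                           legacy_sign = FALSE) {
  if (any(value_at_death <= 0)) .stopf("value_at_death must be positive")
  ch <- 100 * (value_at_day - value_at_death) / value_at_death
  if (legacy_sign) -ch else ch
}

#' Compute per-record percent changes from a measurement table
#'
#' @param measurements a [measurement_table()].
#' @param legacy_sign see [percent_change()].
#' @return data.frame `specimen_id`, `day`, `metric`, `change_percent`.
#' @export
measurement_changes <- function(measurements, legacy_sign = FALSE) {
  measurements <- measurement_table(as.data.frame(measurements))
  data.frame(specimen_id = measurements$specimen_id,
             day = measurements$day,
             metric = measurements$metric,
             change_percent = percent_change(measurements$value_at_death,
                                             measurements$value_at_day,
                                             legacy_sign = legacy_sign),
             stringsAsFactors = FALSE)
}

#' Ordinary least squares of percent change on day, with slope F-test
#'
#' Fits `change_percent ~ day` for one metric and reports slope, intercept,
#' R-squared, the F statistic of zero slope with its (1, n-2) degrees of
#' freedom, and the upper-tail p-value. The identity
#' `F = (R^2 / (1 - R^2)) * (n - 2)` holds for every fit.
#'
#' @param changes data.frame with columns `day`, `change_percent` (one
#'   metric; a `metric` column, if present and unique, is carried through).
#' @param metric optional metric label for the report.
#' @return One-row data.frame: `metric`, `n`, `slope`, `intercept`,
#'   `r_squared`, `F`, `df1`, `df2`, `p_value`; class
#'   `"regression_report"`.
#' @export
fit_change_regression <- function(changes, metric = NULL) {
  .assert_cols(changes, c("day", "change_percent"), "change table")
  if (is.null(metric)) {
    metric <- if (!is.null(changes$metric) &&
                  length(unique(changes$metric)) == 1L) {
      changes$metric[1L]
    } else NA_character_
  }
  n <- nrow(changes)
  if (n < 3L) .stopf("need at least 3 observations")
  if (length(unique(changes$day)) < 2L) {
    .stopf("all observations on the same day: slope undefined")
  }
  fit <- stats::lm(change_percent ~ day, data = changes)
  tss <- sum((changes$change_percent - mean(changes$change_percent))^2)
  # R2 from deviances (robust for perfect and constant fits)
  r2 <- if (tss == 0) 0 else max(0, min(1, 1 - stats::deviance(fit) / tss))
  Fstat <- if (r2 >= 1) Inf else f_from_r_squared(r2, n - 2L)
  out <- data.frame(metric = metric, n = n,
                    slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    r_squared = r2, F = Fstat, df1 = 1L, df2 = n - 2L,
                    p_value = slope_p_from_F(Fstat, n - 2L),
                    stringsAsFactors = FALSE)
  class(out) <- c("regression_report", "data.frame")
  out
}

#' Fit the change regression for every metric in a table
#'
#' @param changes output of [measurement_changes()] (must have a `metric`
#'   column).
#' @return data.frame of one [fit_change_regression()] report per metric.
#' @export
fit_all_metrics <- function(changes) {
  .assert_cols(changes, c("metric", "day", "change_percent"), "change table")
  reports <- lapply(split(changes, changes$metric), fit_change_regression)
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  class(out) <- c("regression_report", "data.frame")
  out
}

#' F statistic of zero slope from R-squared
#'
#' For simple linear regression, `F = (R^2 / (1 - R^2)) * df2` with
#' `df2 = n - 2`. Useful as an internal-consistency check on published
#' regression reports.
#'
#' @param r_squared coefficient of determination in `[0, 1)`.
#' @param df2 denominator degrees of freedom (`n - 2`).
#' @return F statistic.
#' @export
f_from_r_squared <- function(r_squared, df2) {
  if (any(r_squared < 0 | r_squared >= 1)) .stopf("r_squared must be in [0, 1)")
  if (any(df2 < 1)) .stopf("df2 must be >= 1")
  (r_squared / (1 - r_squared)) * df2
}

#' p-value of the slope F-test
#'
#' Upper-tail probability of the F(1, df2) distribution; identical to the
#' two-sided p of the slope's t-test.
#'
#' @param F F statistic (>= 0).
#' @param df2 denominator degrees of freedom.
#' @return p-value in `(0, 1]`.
#' @export
slope_p_from_F <- function(F, df2) {
  if (any(F < 0, na.rm = TRUE)) .stopf("F must be non-negative")
  if (any(df2 < 1)) .stopf("df2 must be >= 1")
  stats::pf(F, 1, df2, lower.tail = FALSE)
}
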