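#' Define one chilling accumulation unit
#'
#' A chilling unit (CU) summarizes cold exposure in a rolling window of
#' `window` days ending on (and including) the output day, from one daily
#' temperature statistic:
#' \describe{
#'   \item{`day_count`}{the number of days in the window on which the
#'     statistic was strictly below the threshold `Th` (units: days);}
#'   \item{`temperature_sum`}{the accumulated deficit
#'     \eqn{\sum (Th - T)} over those sub-threshold days (units: degC days);
#'     see `raw_sum` in [compute_cu()] for the variant that accumulates the
#'     raw temperatures instead.}
#' }
#'
#' @param cu_type `"day_count"` or `"temperature_sum"`.
#' @param temp_stat daily statistic: `"max"`, `"min"` or `"avg"`.
#' @param threshold threshold temperature Th, degC.
#' @param window accumulation window L in days, a positive integer.
#' @return An object of class `cu_config`.
#' @examples
#' cu_config("day_count", "max", 9.5, 46)  # the selected model's unit
#' @export
cu_config <- function(cu_type = c("day_count", "temperature_sum"),
                      temp_stat = c("max", "min", "avg"),
                      threshold, window) {
  cu_type <- match.arg(cu_type)
  temp_stat <- match.arg(temp_stat)
  check_number(threshold, "threshold")
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != round(window))
    stop_("`window` must be a positive integer number of days")
  structure(list(cu_type = cu_type, temp_stat = temp_stat,
                 threshold = threshold, window = as.integer(window)),
            class = "cu_config")
}

#' @export
print.cu_config <- function(x, ...) {
  cat(sprintf("<cu_config> %s of daily %s, Th = %g degC, L = %d days\n",
              x$cu_type, x$temp_stat, x$threshold, x$window))
  invisible(x)
}

temp_column <- function(series, temp_stat) {
  series[[paste0("t", c(max = "max", min = "min", avg = "avg")[temp_stat])]]
}

#' Missing-rate filter for a temperature series
#'
#' Sites are admitted to the analysis only when the missing-data rate of the
#' required daily statistic is at or below `max_rate` (the field convention
#' is 10% or less; the boundary is inclusive). The decision is
#' deterministic and reports the measured rate.
#'
#' @param series a `daily_temps` series (nonempty).
#' @param temp_stat which statistic to assess: `"max"`, `"min"` or `"avg"`.
#' @param max_rate maximum admissible missing proportion (default 0.1).
#' @return A list with elements `accepted` (logical), `rate`, `n_missing`
#'   and `n_days`.
#' @examples
#' s <- gen_temperature_series(climate_params(missing_fraction = 0.05),
#'                             as.Date("2020-01-01"), 100)
#' filter_by_missing_rate(s, "max")
#' @export
filter_by_missing_rate <- function(series, temp_stat = c("max", "min", "avg"),
                                   max_rate = 0.1) {
  temp_stat <- match.arg(temp_stat)
  if (!is.data.frame(series) || nrow(series) == 0L) stop_("empty series")
  check_number(max_rate, "max_rate", lower = 0, upper = 1)
  x <- temp_column(series, temp_stat)
  n_missing <- sum(is.na(x))
  rate <- n_missing / length(x)
  list(accepted = rate <= max_rate, rate = rate,
       n_missing = n_missing, n_days = length(x))
}

#' Impute missing days in a temperature series
#'
#' A single missing day flanked by observed days receives the arithmetic
#' mean of the measurements immediately before and after it; runs of two or
#' more consecutive missing days receive linear interpolation between the
#' flanking observed values (the natural extension of the single-day rule).
#' Non-missing values are preserved exactly. A missing value on the first or
#' last day cannot be interpolated and is rejected naming the date.
#'
#' @param series a `daily_temps` series.
#' @param stats which statistics to impute (default all three).
#' @return The series with `NA`-free columns for the imputed statistics.
#' @examples
#' s <- daily_temps("a", as.Date("2020-01-01") + 0:2,
#'                  tmax = c(5, NA, 7), tmin = c(1, NA, 3),
#'                  tavg = c(3, NA, 5))
#' impute_missing(s)$tmax  # 5 6 7
#' @export
impute_missing <- function(series, stats = c("tmax", "tmin", "tavg")) {
  stopifnot(inherits(series, "daily_temps"))
  n <- nrow(series)
  for (col in stats) {
    x <- series[[col]]
    if (!anyNA(x)) next
    if (is.na(x[1L]))
      stop_("cannot impute %s: missing value on first day %s",
            col, format(series$date[1L]))
    if (is.na(x[n]))
      stop_("cannot impute %s: missing value on last day %s",
            col, format(series$date[n]))
    obs <- which(!is.na(x))
    series[[col]] <- approx(obs, x[obs], xout = seq_len(n),
                            method = "linear")$y
  }
  series
}

#' Compute a chilling-unit series
#'
#' For each date `d` with a full window (the output day and the `L - 1`
#' preceding days), the value is, over days \eqn{\delta} in that window:
#' day count \eqn{\#\{\delta : T(\delta) < Th\}} (strict inequality), or
#' temperature sum \eqn{\sum_{T(\delta) < Th} (Th - T(\delta))} (chilling
#' deficit; with `raw_sum = TRUE`, \eqn{\sum_{T(\delta) < Th} T(\delta)}).
#' The first `L - 1` dates lack a full window and are dropped with a notice.
#'
#' @param series an imputed (NA-free in the used statistic) `daily_temps`.
#' @param config a [cu_config()].
#' @param raw_sum for `temperature_sum` only: accumulate the raw
#'   sub-threshold temperatures instead of the deficit `Th - T`.
#' @param quiet suppress the dropped-leading-dates notice.
#' @return A `cu_series` data frame with columns `date` and `value`, and the
#'   configuration in `attr(, "cu_config")`.
#' @examples
#' s <- daily_temps("a", as.Date("2020-01-01") + 0:4,
#'                  tmax = c(10, 9, 8, 10, 9), tmin = 0, tavg = 5)
#' compute_cu(s, cu_config("day_count", "max", 9.5, 5), quiet = TRUE)$value
#' @export
compute_cu <- function(series, config, raw_sum = FALSE, quiet = FALSE) {
  stopifnot(inherits(series, "daily_temps"), inherits(config, "cu_config"))
  x <- temp_column(series, config$temp_stat)
  if (anyNA(x))
    stop_("series has missing %s values; run impute_missing() first",
          config$temp_stat)
  n <- length(x)
  L <- config$window
  if (n < L)
    stop_("insufficient history: series has %d day(s) but the window is %d",
          n, L)
  below <- x < config$threshold
  z <- switch(config$cu_type,
              day_count = as.numeric(below),
              temperature_sum = if (raw_sum) ifelse(below, x, 0)
                                else ifelse(below, config$threshold - x, 0))
  cz <- cumsum(z)
  value <- cz[L:n] - c(0, cz[seq_len(n - L)])
  if (!quiet && L > 1L)
    message(sprintf("compute_cu: dropping %d leading date(s) without a full %d-day window",
                    L - 1L, L))
  structure(data.frame(date = series$date[L:n], value = value),
            cu_config = config, site_id = series$site_id[1L],
            class = c("cu_series", "data.frame"))
}

#' Maximum chilling unit over a period
#'
#' The period-maximum CU is the geographic suitability statistic: the
#' largest chilling-unit value a site attains over a multi-year period.
#'
#' @param cu_series a `cu_series` from [compute_cu()].
#' @param start,end period bounds (inclusive `Date`s); default the full
#'   series.
#' @return The maximum CU value over the period (a single number).
#' @export
period_max_cu <- function(cu_series, start = NULL, end = NULL) {
  stopifnot(inherits(cu_series, "cu_series"))
  d <- cu_series$date
  keep <- rep(TRUE, length(d))
  if (!is.null(start)) keep <- keep & d >= as.Date(start)
  if (!is.null(end)) keep <- keep & d <= as.Date(end)
  if (!any(keep)) stop_("period does not overlap the CU series")
  max(cu_series$value[keep])
}
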