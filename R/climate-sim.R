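#' Parameters of the synthetic daily-temperature generator
#'
#' The generator emulates a humid temperate station climate (the Tsukuba,
#' Japan field-site climate of the study system): a single cosine seasonal
#' cycle of the daily mean with its minimum anchored in late January
#' (day-of-year 25), a fixed symmetric diurnal spread around the mean,
#' i.i.d. Gaussian day-to-day noise, an optional linear warming trend, and
#' optional station-outage days on which all three daily statistics are
#' missing together.
#'
#' Defaults describe Tsukuba: annual mean 14.5 degC, seasonal amplitude
#' 11 degC (January daily means near 3.5 degC, August near 25.5 degC),
#' diurnal half-range 4.5 degC and day-to-day noise sd 2 degC.
#'
#' @param annual_mean long-term mean of the daily mean temperature, degC.
#' @param seasonal_amplitude half the peak-to-trough seasonal swing of the
#'   daily mean, degC; must be >= 0.
#' @param daily_noise_sd standard deviation of i.i.d. Gaussian day-to-day
#'   noise on the daily mean, degC; must be >= 0.
#' @param diurnal_half_range offset of the daily maximum/minimum around the
#'   daily mean, degC; must be >= 0.
#' @param warming_rate linear trend of the daily mean, degC per year.
#' @param missing_fraction fraction of days marked missing (all three
#'   statistics at once), in \eqn{[0, 1)}.
#' @return An object of class `climate_params`.
#' @seealso [gen_temperature_series()]
#' @export
climate_params <- function(annual_mean = 14.5, seasonal_amplitude = 11,
                           daily_noise_sd = 2, diurnal_half_range = 4.5,
                           warming_rate = 0, missing_fraction = 0) {
  check_number(annual_mean, "annual_mean")
  check_number(seasonal_amplitude, "seasonal_amplitude", lower = 0)
  check_number(daily_noise_sd, "daily_noise_sd", lower = 0)
  check_number(diurnal_half_range, "diurnal_half_range", lower = 0)
  check_number(warming_rate, "warming_rate")
  check_number(missing_fraction, "missing_fraction", lower = 0)
  if (missing_fraction >= 1) stop_("`missing_fraction` must be < 1")
  structure(list(annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 daily_noise_sd = daily_noise_sd,
                 diurnal_half_range = diurnal_half_range,
                 warming_rate = warming_rate,
                 missing_fraction = missing_fraction),
            class = "climate_params")
}

# day-of-year of the seasonal minimum (late January)
COLDEST_DOY <- 25

#' Generate a synthetic daily temperature series
#'
#' Draws a gap-free run of consecutive calendar days. The daily mean is
#' `annual_mean - seasonal_amplitude * cos(2*pi*(doy - 25)/365.25) +
#' warming_rate * years_since_start + N(0, daily_noise_sd^2)`; the daily
#' maximum and minimum are the mean plus/minus `diurnal_half_range`. A
#' fraction `missing_fraction` of days, chosen uniformly at random, has all
#' three statistics set missing. Reproducible under a fixed `seed`.
#'
#' @param params a [climate_params()] object.
#' @param start_date first day, a `Date` (or string coercible to one).
#' @param n_days number of consecutive days, >= 1.
#' @param site_id site identifier carried into the output.
#' @param seed integer seed for this call; the caller's RNG state is
#'   preserved.
#' @return A `daily_temps` data frame with columns `site_id`, `date`,
#'   `tmax`, `tmin`, `tavg` (degC, `NA` on missing days).
#' @examples
#' s <- gen_temperature_series(climate_params(), as.Date("2013-08-01"), 365)
#' range(s$tavg, na.rm = TRUE)
#' @export
gen_temperature_series <- function(params, start_date, n_days,
                                   site_id = "site1", seed = 1L) {
  stopifnot(inherits(params, "climate_params"))
  if (!is.numeric(n_days) || length(n_days) != 1L || is.na(n_days) ||
      n_days < 1)
    stop_("`n_days` must be a positive count, got %s", deparse(n_days))
  n_days <- as.integer(n_days)
  start_date <- as.Date(start_date)
  dates <- start_date + 0:(n_days - 1L)
  doy <- as.integer(format(dates, "%j"))
  years <- as.numeric(dates - start_date) / 365.25

  local_seed(seed, {
    tavg <- params$annual_mean -
      params$seasonal_amplitude * cos(2 * pi * (doy - COLDEST_DOY) / 365.25) +
      params$warming_rate * years +
      rnorm(n_days, sd = params$daily_noise_sd)
    tmax <- tavg + params$diurnal_half_range
    tmin <- tavg - params$diurnal_half_range
    n_miss <- round(params$missing_fraction * n_days)
    if (n_miss > 0) {
      idx <- sample.int(n_days, n_miss)
      tmax[idx] <- tmin[idx] <- tavg[idx] <- NA_real_
    }
    daily_temps(site_id, dates, tmax, tmin, tavg)
  })
}

#' Construct a daily temperature series
#'
#' Builds the `daily_temps` container used throughout the pipeline: one row
#' per consecutive calendar day with daily maximum, minimum and average
#' temperature, each possibly missing. Dates must be strictly increasing
#' with no gaps (absent days are explicit missing rows). On non-missing days
#' `tmin <= tavg <= tmax` is checked; violations are flagged with a warning,
#' not rejected.
#'
#' @param site_id site identifier.
#' @param dates consecutive `Date` values.
#' @param tmax,tmin,tavg daily temperature statistics, degC; `NA` = missing.
#' @return A data frame of class `daily_temps`.
#' @export
daily_temps <- function(site_id, dates, tmax, tmin, tavg) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n == 0L) stop_("empty series")
  if (n > 1L && any(diff(as.integer(dates)) != 1L))
    stop_("`dates` must be consecutive calendar days with no gaps")
  stopifnot(length(tmax) == n, length(tmin) == n, length(tavg) == n)
  ok <- !is.na(tmax) & !is.na(tmin) & !is.na(tavg)
  bad <- ok & (tmin > tavg | tavg > tmax)
  if (any(bad))
    warning(sprintf("%d day(s) violate tmin <= tavg <= tmax (first: %s)",
                    sum(bad), format(dates[which(bad)[1L]])), call. = FALSE)
  structure(
    data.frame(site_id = rep_len(as.character(site_id), n), date = dates,
               tmax = as.numeric(tmax), tmin = as.numeric(tmin),
               tavg = as.numeric(tavg)),
    class = c("daily_temps", "data.frame"))
}

#' The data-generating ("true") QY model of the synthetic-data module
#'
#' QY observations are generated as
#' `inv_logit(a * CU(date) + b + e)`, `e ~ N(0, obs_sd^2)` independently per
#' leaf, where CU is the chilling unit defined by `cu_config`. The defaults
#' are the selected model family of the study system — the count of days
#' with daily maximum temperature below 9.5 degC over the trailing 46 days —
#' with slope and intercept chosen so predicted QY spans roughly 0.70 (no
#' chilling) down to 0.05 (saturated chilling, CU = 46).
#'
#' @param cu_config a [cu_config()] chilling-unit definition.
#' @param a slope on the logit scale per CU unit.
#' @param b intercept on the logit scale.
#' @param obs_sd residual standard deviation on the logit scale, >= 0.
#' @return An object of class `true_model`.
#' @export
true_model <- function(cu_config = chillqy::cu_config("day_count", "max", 9.5, 46),
                       a = -0.082, b = 0.85, obs_sd = 0.1) {
  stopifnot(inherits(cu_config, "cu_config"))
  check_number(a, "a"); check_number(b, "b")
  check_number(obs_sd, "obs_sd", lower = 0)
  structure(list(cu_config = cu_config, a = a, b = b, obs_sd = obs_sd),
            class = "true_model")
}

#' Generate synthetic QY observations from a temperature series
#'
#' Emulates the biweekly November-March leaf quantum-yield survey: on each
#' sampling date, for each clonal line and replicate leaf, QY is drawn as
#' `inv_logit(a * CU(date) + b + e)` with `e ~ N(0, obs_sd^2)` independent
#' per observation. All generated QY lie strictly inside (0, 1).
#'
#' The series must provide at least `window` days of history up to and
#' including the first sampling date so the chilling unit has a full
#' window; otherwise the call is rejected naming the shortfall in days.
#' Series with missing days are imputed internally (see
#' [impute_missing()]).
#'
#' @param series a `daily_temps` series covering the sampling dates.
#' @param truth a [true_model()].
#' @param first_date,last_date first and last allowed sampling dates.
#' @param interval days between sampling dates (default 14, biweekly).
#' @param n_lines number of clonal lines.
#' @param n_replicates leaves measured per line and date.
#' @param seed integer seed for this call.
#' @return A `qy_obs` data frame with columns `site_id`, `date`, `line`,
#'   `replicate`, `qy`.
#' @examples
#' s <- gen_temperature_series(climate_params(), as.Date("2013-08-01"), 365)
#' o <- gen_qy_observations(s, true_model(),
#'                          first_date = as.Date("2013-11-01"),
#'                          last_date = as.Date("2014-03-31"))
#' table(o$date)[1:3]
#' @export
gen_qy_observations <- function(series, truth, first_date, last_date,
                                interval = 14L, n_lines = 2L,
                                n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(series, "daily_temps"), inherits(truth, "true_model"))
  first_date <- as.Date(first_date); last_date <- as.Date(last_date)
  if (last_date < first_date) stop_("`last_date` precedes `first_date`")
  sampling <- seq(first_date, last_date, by = as.integer(interval))
  L <- truth$cu_config$window
  history <- as.integer(first_date - series$date[1L]) + 1L
  if (history < L)
    stop_("insufficient temperature history before first sampling date: need %d days, have %d (short by %d)",
          L, history, L - history)
  if (max(sampling) > series$date[nrow(series)])
    stop_("series ends %s, before last sampling date %s",
          format(series$date[nrow(series)]), format(max(sampling)))
  if (anyNA(series[c("tmax", "tmin", "tavg")])) series <- impute_missing(series)
  cu <- compute_cu(series, truth$cu_config, quiet = TRUE)
  cu_at <- cu$value[match(sampling, cu$date)]

  lines <- sprintf("line%02d", seq_len(n_lines))
  grid <- expand.grid(replicate = seq_len(n_replicates), line = lines,
                      date = sampling, stringsAsFactors = FALSE)
  local_seed(seed, {
    eta <- truth$a * cu_at[match(grid$date, sampling)] + truth$b +
      rnorm(nrow(grid), sd = truth$obs_sd)
    qy_obs(series$site_id[1L], grid$date, grid$line, grid$replicate,
           plogis(eta))
  })
}

#' Construct a QY observation table
#'
#' @param site_id site identifier.
#' @param date observation dates.
#' @param line clonal-line labels.
#' @param replicate replicate (leaf) indices.
#' @param qy quantum yield values in \eqn{[0, 1]}.
#' @return A data frame of class `qy_obs`.
#' @export
qy_obs <- function(site_id, date, line, replicate, qy) {
  if (any(!is.finite(qy)) || any(qy < 0) || any(qy > 1))
    stop_("`qy` must lie in [0, 1]")
  n <- length(qy)
  structure(
    data.frame(site_id = rep_len(as.character(site_id), n),
               date = as.Date(date), line = as.character(line),
               replicate = as.integer(replicate), qy = as.numeric(qy)),
    class = c("qy_obs", "data.frame"))
}
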