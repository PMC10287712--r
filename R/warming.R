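#' Annual minimum predicted QY per season
#'
#' Runs the fitted chilling-unit model over a long temperature record and,
#' for each cold season (default window Oct 1 - Mar 31, labelled by its
#' start year), takes the minimum of the daily predicted QY
#' `inv_logit(a * CU(d) + b)`. Seasons whose window is not fully covered by
#' the CU series are skipped and listed.
#'
#' @param series a `daily_temps` record spanning the seasons (imputed
#'   internally if needed).
#' @param fit a `cu_fit` carrying its `cu_config`.
#' @param season_start,season_end month-day strings (`"10-01"`,
#'   `"03-31"`); the end falls in the following calendar year when it
#'   precedes the start.
#' @return A data frame with columns `season` (start year), `min_qy`, and
#'   skipped seasons in `attr(, "skipped")`.
#' @export
seasonal_min_qy <- function(series, fit, season_start = "10-01",
                            season_end = "03-31") {
  stopifnot(inherits(fit, "cu_fit"), !is.null(fit$cu_config))
  if (anyNA(series[c("tmax", "tmin", "tavg")])) series <- impute_missing(series)
  cu <- compute_cu(series, fit$cu_config, quiet = TRUE)
  qy <- plogis(fit$a * cu$value + fit$b)
  years <- sort(unique(as.integer(format(series$date, "%Y"))))
  wraps <- as.Date(paste0("2001-", season_end)) <
    as.Date(paste0("2001-", season_start))
  rows <- list(); skipped <- integer()
  for (yr in years) {
    s0 <- as.Date(sprintf("%d-%s", yr, season_start))
    s1 <- as.Date(sprintf("%d-%s", yr + as.integer(wraps), season_end))
    if (s0 < cu$date[1L] || s1 > cu$date[length(cu$date)]) {
      if (s1 >= series$date[1L] && s0 <= series$date[nrow(series)])
        skipped <- c(skipped, yr)
      next
    }
    sel <- cu$date >= s0 & cu$date <= s1
    rows[[length(rows) + 1L]] <- data.frame(season = yr,
                                            min_qy = min(qy[sel]))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(season = integer(), min_qy = numeric())
  attr(out, "skipped") <- skipped
  out
}

#' Linear warming trend of annual minimum QY
#'
#' Ordinary least-squares regression of a site's annual-minimum predicted
#' QY on the season start year, with the standard regression confidence and
#' prediction intervals. Needs at least 3 seasons.
#'
#' @param annual a data frame with columns `season` (year) and `min_qy`,
#'   as from [seasonal_min_qy()].
#' @param site_id optional identifier carried in the result.
#' @return An object of class `qy_trend`: list with `slope` (QY per year),
#'   `intercept` (QY at year 0), `n_seasons`, `site_id` and the underlying
#'   `lm` fit.
#' @examples
#' tr <- fit_trend(data.frame(season = 1950:1959,
#'                            min_qy = 0.05 + 0.001 * (0:9)))
#' tr$slope  # 0.001, i.e. 0.01 per decade
#' @export
fit_trend <- function(annual, site_id = NULL) {
  stopifnot(is.data.frame(annual), all(c("season", "min_qy") %in% names(annual)))
  if (nrow(annual) < 3L)
    stop_("need at least 3 seasons to fit a trend, got %d", nrow(annual))
  fit <- lm(min_qy ~ season, data = annual)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_seasons = nrow(annual), site_id = site_id, lm = fit),
            class = "qy_trend")
}

#' @export
print.qy_trend <- function(x, ...) {
  cat(sprintf("Annual-minimum-QY trend%s: %+.4f QY per decade over %d seasons\n",
              if (is.null(x$site_id)) "" else paste0(" (", x$site_id, ")"),
              10 * x$slope, x$n_seasons))
  invisible(x)
}

#' @method predict qy_trend
#' @export
predict.qy_trend <- function(object, target_year,
                             interval = c("none", "confidence", "prediction"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  nd <- data.frame(season = as.numeric(target_year))
  if (interval == "none") as.numeric(predict(object$lm, nd))
  else as.data.frame(predict(object$lm, nd, interval = interval,
                             level = level))
}

#' Extrapolate a trend to a target year
#'
#' Evaluates the regression line at `target_year` and clamps the result into
#' \eqn{[0, 1]} (QY is a proportion). At a year inside the fitted range this
#' equals the regression line's value there — there is no discontinuity
#' between interpolation and extrapolation.
#'
#' @param trend a `qy_trend`.
#' @param target_year year(s) at which to predict.
#' @return Predicted annual-minimum QY, clamped to \eqn{[0, 1]}.
#' @export
extrapolate <- function(trend, target_year) {
  stopifnot(inherits(trend, "qy_trend"))
  pmin(pmax(trend$slope * as.numeric(target_year) + trend$intercept, 0), 1)
}

#' Count sites whose predicted minimum QY exceeds a threshold
#'
#' "Exceeds" is strict (`>`): a site exactly at the threshold does not
#' count.
#'
#' @param values per-site predicted annual-minimum QY.
#' @param threshold suitability threshold (default 0.20; 0.4 is the named
#'   alternative convention).
#' @return The count of sites with `value > threshold`.
#' @examples
#' count_suitable_sites(c(0.1, 0.2, 0.3), 0.2)  # 1
#' @export
count_suitable_sites <- function(values, threshold = 0.20) {
  if (any(!is.finite(values))) stop_("site values must be finite")
  sum(values > threshold)
}

#' Map the suitability decision boundary for a target year
#'
#' Trains a classification SVM on per-site suitability booleans and
#' predicts a regular lat/lon grid; a thin wrapper over
#' [svm_interpolate()] in classification mode.
#'
#' @param sites data frame with `lat`, `lon` and logical `value`
#'   (suitable).
#' @param grid_resolution lattice spacing in degrees (default 0.1, the
#'   national-grid convention; 0.05 is the finer alternative).
#' @param ... passed to [svm_interpolate()].
#' @return A `suitability_grid` with logical `value`.
#' @export
map_decision_boundary <- function(sites, grid_resolution = 0.1, ...) {
  svm_interpolate(sites, grid_resolution = grid_resolution,
                  mode = "classification", ...)
}
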