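#' Predict QY with confidence and prediction intervals
#'
#' Predictions and intervals are constructed on the logit scale using the
#' standard simple-regression geometry with the unbiased variance
#' \eqn{s^2 = RSS/(n-2)} and Student-t quantiles: the mean-response
#' confidence interval is
#' \eqn{\hat y \pm t_{1-\alpha/2, n-2}\, s \sqrt{1/n + (x-\bar x)^2/S_{xx}}}
#' and the prediction interval for a new observation adds \eqn{+1} under the
#' square root. The inverse logit is monotone, so the logit-scale bounds map
#' to QY-scale bounds endpoint-by-endpoint.
#'
#' @param object a `cu_fit`.
#' @param newdata CU values: a numeric vector, or a data frame with a `cu`
#'   column. Defaults to the training CU values.
#' @param interval `"none"`, `"confidence"` or `"prediction"`.
#' @param level interval coverage level (default 0.95).
#' @param scale `"qy"` (default) or `"logit"`.
#' @param ... unused.
#' @return With `interval = "none"`, a vector of predictions; otherwise a
#'   data frame with columns `cu`, `fit`, `lwr`, `upr`.
#' @method predict cu_fit
#' @export
predict.cu_fit <- function(object, newdata = NULL,
                           interval = c("none", "confidence", "prediction"),
                           level = 0.95, scale = c("qy", "logit"), ...) {
  interval <- match.arg(interval)
  scale <- match.arg(scale)
  cu <- if (is.null(newdata)) object$data$cu
        else if (is.data.frame(newdata)) newdata$cu
        else as.numeric(newdata)
  if (is.null(cu)) stop_("`newdata` must be a numeric vector or have a `cu` column")
  n <- object$n_obs
  if (n < 3L) stop_("fit has fewer than 3 observations")
  eta <- object$a * cu + object$b
  to_scale <- if (scale == "qy") plogis else identity
  if (interval == "none") return(to_scale(eta))
  s <- sqrt(object$rss / (n - 2))
  lev <- qt(1 - (1 - level) / 2, df = n - 2)
  h <- 1 / n + (cu - object$xbar)^2 / object$sxx
  half <- lev * s * sqrt(h + as.numeric(interval == "prediction"))
  data.frame(cu = cu, fit = to_scale(eta), lwr = to_scale(eta - half),
             upr = to_scale(eta + half))
}

#' Interval predictions carrying both the confidence and prediction band
#'
#' Convenience wrapper producing, per CU value, the point prediction on the
#' QY scale together with the 95% mean-response confidence bounds and the
#' 95% new-observation prediction bounds. By construction
#' `pi_low <= ci_low <= qy_hat <= ci_high <= pi_high`, all in \eqn{[0,1]}.
#'
#' @param fit a `cu_fit`.
#' @param cu_values CU values at which to predict.
#' @param level coverage level (default 0.95).
#' @param dates optional dates attached to the rows.
#' @return A data frame with columns `date` (if given), `cu`, `qy_hat`,
#'   `ci_low`, `ci_high`, `pi_low`, `pi_high`.
#' @export
predict_with_intervals <- function(fit, cu_values, level = 0.95,
                                   dates = NULL) {
  ci <- predict(fit, cu_values, interval = "confidence", level = level)
  pi <- predict(fit, cu_values, interval = "prediction", level = level)
  out <- data.frame(cu = ci$cu, qy_hat = ci$fit,
                    ci_low = ci$lwr, ci_high = ci$upr,
                    pi_low = pi$lwr, pi_high = pi$upr)
  if (!is.null(dates)) out <- cbind(date = as.Date(dates), out)
  out
}

#' Count observations falling inside an interval band
#'
#' Counts observed QY values lying inside the chosen band, endpoints
#' inclusive. When both tables carry a `date` column, observations are
#' matched to predictions by date; otherwise they are matched by position.
#'
#' @param predictions output of [predict_with_intervals()].
#' @param observed observed QY values: a numeric vector, or a data frame
#'   with columns `qy` and optionally `date`.
#' @param interval_kind `"confidence"` or `"prediction"`.
#' @return A list with `n_within` and `n_total`.
#' @export
coverage_count <- function(predictions, observed,
                           interval_kind = c("confidence", "prediction")) {
  interval_kind <- match.arg(interval_kind)
  if (is.data.frame(observed)) {
    if (!is.null(observed$date) && !is.null(predictions$date)) {
      idx <- match(observed$date, predictions$date)
      if (anyNA(idx))
        stop_("observation date(s) have no prediction: %s",
              paste(format(unique(observed$date[is.na(idx)])), collapse = ", "))
      predictions <- predictions[idx, ]
    }
    observed <- observed$qy
  }
  if (length(observed) != nrow(predictions))
    stop_("lengths of predictions and observations differ")
  lo <- if (interval_kind == "confidence") predictions$ci_low else predictions$pi_low
  hi <- if (interval_kind == "confidence") predictions$ci_high else predictions$pi_high
  list(n_within = sum(observed >= lo & observed <= hi),
       n_total = length(observed))
}

#' Correlation and predictive coefficient of determination
#'
#' `pearson_r` is the sample correlation between predictions and
#' observations; `r_squared_pred` is the predictive coefficient of
#' determination \eqn{1 - \sum(obs - pred)^2 / \sum(obs - \bar{obs})^2}. It
#' can be negative for a model worse than the observed mean; it is reported
#' as computed, never clipped. Metrics are computed on the declared scale.
#'
#' @param predicted,observed equal-length vectors (length >= 3) on the QY
#'   scale.
#' @param scale `"qy"` or `"logit"` (transforms both vectors first).
#' @param eps logit clamp bound when `scale = "logit"`.
#' @return A list with `pearson_r` and `r_squared_pred`.
#' @export
prediction_metrics <- function(predicted, observed, scale = c("qy", "logit"),
                               eps = 1e-3) {
  scale <- match.arg(scale)
  if (length(predicted) != length(observed)) stop_("length mismatch")
  if (length(observed) < 3L) stop_("need at least 3 points")
  if (scale == "logit") {
    predicted <- logit(predicted, eps = eps)
    observed <- logit(observed, eps = eps)
  }
  if (sd(observed) == 0)
    stop_("observed values are constant: correlation undefined")
  list(pearson_r = cor(predicted, observed),
       r_squared_pred = 1 - sum((observed - predicted)^2) /
         sum((observed - mean(observed))^2))
}

#' Validate a fitted model against one season of observations
#'
#' Computes the CU series for the fit's configuration over the season,
#' predicts QY with 95% confidence and prediction bands at each
#' observation's date, counts observations inside the chosen band, and
#' reports the correlation and predictive R-squared (on the logit scale, as
#' for the fit itself).
#'
#' @param fit a `cu_fit` (trained on other seasons for an out-of-sample
#'   validation).
#' @param series the `daily_temps` record covering the season plus window
#'   history.
#' @param observations `qy_obs` rows for the season.
#' @param season label for the report.
#' @param interval_kind band used for the coverage count (default
#'   `"confidence"`, mirroring the published figures; `"prediction"`
#'   available).
#' @param aggregation,eps see [assemble_design()].
#' @return An object of class `qy_validation`: list with `season`, `table`
#'   (per-point date, cu, qy_obs, qy_hat, bounds, within), `n_within`,
#'   `n_points`, `interval_kind`, `pearson_r`, `r_squared_pred`.
#' @export
validate_season <- function(fit, series, observations, season = "season",
                            interval_kind = c("confidence", "prediction"),
                            aggregation = c("per_line_date_mean",
                                            "per_observation"),
                            eps = 1e-3) {
  interval_kind <- match.arg(interval_kind)
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(fit, "cu_fit"), !is.null(fit$cu_config))
  if (anyNA(series[c("tmax", "tmin", "tavg")])) series <- impute_missing(series)
  cu <- compute_cu(series, fit$cu_config, quiet = TRUE)
  design <- assemble_design(cu, observations, aggregation = aggregation,
                            eps = eps)
  pred <- predict_with_intervals(fit, design$cu, dates = design$date)
  cover <- coverage_count(pred, data.frame(qy = design$qy),
                          interval_kind = interval_kind)
  met <- prediction_metrics(pred$qy_hat, design$qy, scale = "logit",
                            eps = eps)
  tab <- data.frame(date = design$date, line = design$line, cu = design$cu,
                    qy_obs = design$qy, qy_hat = pred$qy_hat,
                    ci_low = pred$ci_low, ci_high = pred$ci_high,
                    pi_low = pred$pi_low, pi_high = pred$pi_high)
  lo <- if (interval_kind == "confidence") tab$ci_low else tab$pi_low
  hi <- if (interval_kind == "confidence") tab$ci_high else tab$pi_high
  tab$within <- tab$qy_obs >= lo & tab$qy_obs <= hi
  structure(list(season = season, table = tab,
                 n_within = cover$n_within, n_points = cover$n_total,
                 interval_kind = interval_kind,
                 pearson_r = met$pearson_r,
                 r_squared_pred = met$r_squared_pred),
            class = "qy_validation")
}

#' @export
print.qy_validation <- function(x, ...) {
  cat(sprintf("QY validation, %s: %d/%d points within the 95%% %s interval\n",
              x$season, x$n_within, x$n_points, x$interval_kind))
  cat(sprintf("  r = %.3f, predictive R^2 = %.3f (logit scale)\n",
              x$pearson_r, x$r_squared_pred))
  invisible(x)
}
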