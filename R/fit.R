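#' Pair chilling-unit values with logit-transformed QY responses
#'
#' Builds the regression design for one chilling-unit configuration: each
#' response is paired with the CU value on its observation date. With
#' aggregation `"per_line_date_mean"` (the default) the replicate leaves
#' within each (line, date) cell are averaged on the QY scale before the
#' logit transform; `"per_observation"` keeps every leaf as its own row.
#'
#' @param cu_series a `cu_series` covering every observation date.
#' @param observations a `qy_obs` data frame (or one with columns `date`,
#'   `line`, `replicate`, `qy`).
#' @param aggregation `"per_line_date_mean"` or `"per_observation"`.
#' @param eps logit clamp bound, see [logit()].
#' @return A data frame with columns `date`, `line`, `cu`, `qy`,
#'   `logit_qy`.
#' @export
assemble_design <- function(cu_series, observations,
                            aggregation = c("per_line_date_mean",
                                            "per_observation"),
                            eps = 1e-3) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(cu_series, "cu_series"))
  if (!is.data.frame(observations) || nrow(observations) == 0L)
    stop_("empty observation set")
  miss <- setdiff(format(unique(observations$date)), format(cu_series$date))
  if (length(miss))
    stop_("observation date(s) lacking CU coverage: %s",
          paste(miss, collapse = ", "))
  if (aggregation == "per_line_date_mean") {
    agg <- stats::aggregate(qy ~ line + date, data = observations, FUN = mean)
    observations <- agg[order(agg$date, agg$line), ]
  }
  cu <- cu_series$value[match(observations$date, cu_series$date)]
  data.frame(date = observations$date, line = observations$line,
             cu = cu, qy = observations$qy,
             logit_qy = logit(observations$qy, eps = eps),
             row.names = NULL)
}

# Closed-form simple OLS with the ML (RSS/n) variance convention used for
# AIC. Returns NULL when the predictor is (numerically) constant.
ols_ml <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x) - sx^2 / n
  sxy <- sum(x * y) - sx * sy / n
  syy <- sum(y * y) - sy^2 / n
  if (!is.finite(sxx) || sxx <= 1e-12) return(NULL)
  a <- sxy / sxx
  b <- (sy - a * sx) / n
  rss <- max(syy - a * sxy, 0)
  sigma2 <- rss / n
  log_lik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  list(a = a, b = b, sigma = sqrt(sigma2), rss = rss, sxx = sxx,
       xbar = sx / n, n = n, log_lik = log_lik, aic = 6 - 2 * log_lik,
       r_squared = if (syy > 0) 1 - rss / syy else NA_real_)
}

#' Fit the logit-linear QY model for one chilling unit
#'
#' Ordinary least squares of `logit(QY)` on the CU value:
#' \eqn{\mathrm{logit}(QY) = a \cdot CU + b + \epsilon}. The residual
#' variance is the maximum-likelihood estimate \eqn{\hat\sigma^2 = RSS/n}
#' (the Gaussian-glm convention), the Gaussian log-likelihood is
#' \eqn{-n/2\,(\log(2\pi\hat\sigma^2) + 1)}, and the AIC counts
#' \eqn{k = 3} parameters (slope, intercept, residual variance):
#' \eqn{AIC = 6 - 2\,\log L}.
#'
#' `fit_logit_linear()` takes ready-made `(cu, logit_qy)` vectors;
#' `fit_cu_model()` is the full fitting entry point that derives the CU
#' series from a temperature record for a given configuration, assembles
#' the design and fits.
#'
#' @param cu chilling-unit values (not constant; length >= 3).
#' @param logit_qy responses on the logit scale, same length.
#' @param config optionally, the [cu_config()] the CU values came from.
#' @return An object of class `cu_fit` with components `a`, `b`, `sigma`
#'   (ML), `n_obs`, `log_lik`, `aic`, `r_squared`, the training `data`, and
#'   the `cu_config`. Methods: [print()], [summary()], [coef()],
#'   [predict.cu_fit()], [residuals()], [fitted()], [simulate()],
#'   [plot.cu_fit()], [logLik()].
#' @examples
#' fit <- fit_logit_linear(c(0, 10, 20, 30), c(1, 0.2, -0.6, -1.4))
#' coef(fit)  # a = -0.08, b = 1
#' @export
fit_logit_linear <- function(cu, logit_qy, config = NULL) {
  if (length(cu) != length(logit_qy)) stop_("`cu` and `logit_qy` lengths differ")
  if (length(cu) < 3L) stop_("need at least 3 observation pairs, got %d",
                             length(cu))
  if (anyNA(cu) || anyNA(logit_qy)) stop_("missing values in the design")
  fit <- ols_ml(cu, logit_qy)
  if (is.null(fit))
    stop_("constant CU predictor: the slope is unidentifiable")
  structure(list(a = fit$a, b = fit$b, sigma = fit$sigma, n_obs = fit$n,
                 rss = fit$rss, sxx = fit$sxx, xbar = fit$xbar,
                 log_lik = fit$log_lik, aic = fit$aic,
                 r_squared = fit$r_squared,
                 data = data.frame(cu = cu, logit_qy = logit_qy,
                                   qy = plogis(logit_qy)),
                 cu_config = config),
            class = "cu_fit")
}

#' @param series a `daily_temps` temperature record (imputed internally if
#'   it has missing days).
#' @param observations a `qy_obs` table.
#' @param aggregation,eps see [assemble_design()].
#' @rdname fit_logit_linear
#' @export
fit_cu_model <- function(series, observations, config,
                         aggregation = c("per_line_date_mean",
                                         "per_observation"),
                         eps = 1e-3) {
  stopifnot(inherits(series, "daily_temps"), inherits(config, "cu_config"))
  if (anyNA(series[c("tmax", "tmin", "tavg")])) series <- impute_missing(series)
  cu <- compute_cu(series, config, quiet = TRUE)
  design <- assemble_design(cu, observations, aggregation = aggregation,
                            eps = eps)
  fit <- fit_logit_linear(design$cu, design$logit_qy, config = config)
  fit$data <- design
  fit
}

#' @export
print.cu_fit <- function(x, digits = 4, ...) {
  cat("Logit-linear QY chilling-unit model\n")
  if (!is.null(x$cu_config))
    cat(sprintf("  unit: %s of daily %s, Th = %g degC, L = %d days\n",
                x$cu_config$cu_type, x$cu_config$temp_stat,
                x$cu_config$threshold, x$cu_config$window))
  cat(sprintf("  logit(QY) = %s * CU + %s   (sigma_ML = %s, n = %d)\n",
              signif(x$a, digits), signif(x$b, digits),
              signif(x$sigma, digits), x$n_obs))
  cat(sprintf("  logLik = %s, AIC = %s, R^2 = %s\n",
              signif(x$log_lik, digits + 2), signif(x$aic, digits + 2),
              signif(x$r_squared, digits)))
  invisible(x)
}

#' @method coef cu_fit
#' @export
coef.cu_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
logLik.cu_fit <- function(object, ...)
  structure(object$log_lik, df = 3L, nobs = object$n_obs, class = "logLik")

#' @method fitted cu_fit
#' @export
fitted.cu_fit <- function(object, scale = c("qy", "logit"), ...) {
  scale <- match.arg(scale)
  eta <- object$a * object$data$cu + object$b
  if (scale == "qy") plogis(eta) else eta
}

#' @export
residuals.cu_fit <- function(object, scale = c("logit", "qy"), ...) {
  scale <- match.arg(scale)
  if (scale == "logit") object$data$logit_qy - fitted(object, "logit")
  else object$data$qy - fitted(object, "qy")
}

#' @export
summary.cu_fit <- function(object, ...) {
  n <- object$n_obs
  s2 <- object$rss / (n - 2)
  se_a <- sqrt(s2 / object$sxx)
  se_b <- sqrt(s2 * (1 / n + object$xbar^2 / object$sxx))
  tab <- cbind(Estimate = c(a = object$a, b = object$b),
               `Std. Error` = c(se_a, se_b),
               `t value` = c(object$a / se_a, object$b / se_b))
  tab <- cbind(tab, `Pr(>|t|)` = 2 * stats::pt(-abs(tab[, "t value"]),
                                               df = n - 2))
  structure(list(fit = object, coefficients = tab, s = sqrt(s2),
                 df_residual = n - 2), class = "summary.cu_fit")
}

#' @export
print.summary.cu_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (interval-scale s = ", signif(x$s, 4),
      ", df = ", x$df_residual, "):\n", sep = "")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Simulate new QY observations from a fitted model
#'
#' Draws new logit-scale responses at the training CU values with residual
#' standard deviation `s = sqrt(RSS/(n-2))` and maps them back to the QY
#' scale.
#'
#' @param object a `cu_fit`.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed (caller RNG state preserved).
#' @param ... unused.
#' @return A data frame with `nsim` columns `sim_1`, ... of QY values.
#' @export
simulate.cu_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n_obs
  s <- sqrt(object$rss / (n - 2))
  mu <- object$a * object$data$cu + object$b
  local_seed(seed, {
    out <- as.data.frame(replicate(nsim, plogis(mu + rnorm(n, sd = s)),
                                   simplify = FALSE))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot a fitted chilling-unit model
#'
#' Scatter of observed QY against the chilling unit with the fitted curve
#' and its 95% confidence band (mapped through the inverse logit).
#'
#' @param x a `cu_fit`.
#' @param level band coverage level.
#' @param n_grid points along the CU axis.
#' @param ... passed to [plot()].
#' @method plot cu_fit
#' @export
plot.cu_fit <- function(x, level = 0.95, n_grid = 200, ...) {
  cu_grid <- seq(min(x$data$cu), max(x$data$cu), length.out = n_grid)
  band <- predict(x, cu_grid, interval = "confidence", level = level)
  plot(x$data$cu, x$data$qy, xlab = "chilling unit",
       ylab = "quantum yield (QY)", ylim = c(0, 1), ...)
  polygon(c(cu_grid, rev(cu_grid)), c(band$lwr, rev(band$upr)),
          col = adjustcolor("steelblue", 0.25), border = NA)
  lines(cu_grid, band$fit, col = "steelblue", lwd = 2)
  invisible(x)
}
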