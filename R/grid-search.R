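#' Exhaustive AIC model search over the chilling-unit grid
#'
#' Fits the logit-linear QY model once per chilling-unit configuration in
#' the grid (the default grid has 25,620 configurations: 2 CU types x 3
#' temperature statistics x 61 thresholds x 70 windows) and selects the
#' minimum-AIC fit. The full fit table is retained so the AIC surface over
#' threshold x window can be inspected per family ([plot.cu_grid_search()]).
#'
#' The fit for every window at a given threshold shares one cumulative-sum
#' pass over the temperature series, so the full search runs in well under a
#' second on typical multi-season inputs; results are identical to fitting
#' each configuration separately.
#'
#' Configurations whose CU values are constant over the observation dates
#' (e.g. a threshold below every recorded temperature) are unidentifiable;
#' they are recorded as failed with `AIC = +Inf` rather than dropped, so
#' the AIC table stays rectangular. The search fails only if every
#' configuration fails. AIC ties within `tie_tol` are broken by grid order
#' (first enumerated wins) and reported in `tie_report`.
#'
#' @param series a `daily_temps` record covering every observation date plus
#'   at least the largest window of history (imputed internally if needed;
#'   it must pass the missing-rate filter first if that policy applies).
#' @param observations a `qy_obs` table.
#' @param spec a [grid_spec()].
#' @param aggregation,eps see [assemble_design()].
#' @param tie_tol AIC tie tolerance (default 1e-9).
#' @return An object of class `cu_grid_search`: list with `fits` (data
#'   frame, one row per configuration: `cu_type`, `temp_stat`, `threshold`,
#'   `window`, `a`, `b`, `sigma`, `n_obs`, `log_lik`, `aic`, `r_squared`,
#'   `converged`), `best` (the minimum-AIC `cu_fit`), `best_index`,
#'   `tie_report`, `spec`, `aggregation`.
#' @examples
#' s <- gen_temperature_series(climate_params(), as.Date("2013-08-01"), 300)
#' o <- gen_qy_observations(s, true_model(),
#'                          first_date = as.Date("2013-11-01"),
#'                          last_date = as.Date("2014-03-31"))
#' small <- grid_spec(threshold_ranges = list(max = c(8, 11)),
#'                    threshold_step = 0.5, window_range = c(30, 60),
#'                    window_step = 10, cu_types = "day_count",
#'                    temp_stats = "max")
#' gs <- cu_grid_search(s, o, small)
#' gs$best
#' @export
cu_grid_search <- function(series, observations, spec = grid_spec(),
                           aggregation = c("per_line_date_mean",
                                           "per_observation"),
                           eps = 1e-3, tie_tol = 1e-9) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(series, "daily_temps"), inherits(spec, "grid_spec"))
  if (!is.data.frame(observations) || nrow(observations) == 0L)
    stop_("empty observation set")
  if (anyNA(series[c("tmax", "tmin", "tavg")])) series <- impute_missing(series)

  # response rows (aggregated once; CU depends only on the date)
  if (aggregation == "per_line_date_mean") {
    agg <- stats::aggregate(qy ~ line + date, data = observations, FUN = mean)
    resp <- agg[order(agg$date, agg$line), ]
  } else {
    resp <- observations[order(observations$date, observations$line), ]
  }
  y <- logit(resp$qy, eps = eps)
  d_idx <- match(resp$date, series$date)
  if (anyNA(d_idx))
    stop_("observation date(s) outside the temperature series: %s",
          paste(format(unique(resp$date[is.na(d_idx)])), collapse = ", "))
  Ls <- grid_windows(spec)
  if (min(d_idx) < max(Ls))
    stop_("observation date %s lacks a full %d-day window of temperature history",
          format(resp$date[which.min(d_idx)]), max(Ls))

  m <- length(y)
  sy <- sum(y); syy_c <- sum(y^2) - sy^2 / m
  nL <- length(Ls)

  blocks <- vector("list", length(spec$cu_types) * length(spec$temp_stats))
  bi <- 0L
  for (cu_type in spec$cu_types) {
    for (stat in spec$temp_stats) {
      x_t <- temp_column(series, stat)
      ths <- grid_thresholds(spec, stat)
      nt <- length(ths)
      a_v <- b_v <- s_v <- ll_v <- aic_v <- r2_v <- numeric(nt * nL)
      ok_v <- logical(nt * nL)
      for (i in seq_along(ths)) {
        th <- ths[i]
        below <- x_t < th
        z <- if (cu_type == "day_count") as.numeric(below)
             else ifelse(below, th - x_t, 0)
        cz <- c(0, cumsum(z))
        # X[l, j] = CU with window Ls[l] on the date of response row j
        X <- matrix(cz[rep(d_idx + 1L, each = nL)] -
                      cz[outer(Ls, d_idx, function(L, d) d + 1L - L)],
                    nrow = nL)
        Sx <- rowSums(X)
        sxx <- rowSums(X * X) - Sx^2 / m
        sxy <- as.vector(X %*% y) - Sx * sy / m
        ok <- sxx > 1e-12
        a <- ifelse(ok, sxy / sxx, NA_real_)
        b <- (sy - ifelse(ok, a, 0) * Sx) / m
        rss <- pmax(syy_c - ifelse(ok, a * sxy, NA_real_), 0)
        sigma2 <- rss / m
        ll <- ifelse(sigma2 > 0, -m / 2 * (log(2 * pi * sigma2) + 1), Inf)
        idx <- (i - 1L) * nL + seq_len(nL)
        a_v[idx] <- a
        b_v[idx] <- ifelse(ok, b, NA_real_)
        s_v[idx] <- ifelse(ok, sqrt(sigma2), NA_real_)
        ll_v[idx] <- ifelse(ok, ll, NA_real_)
        aic_v[idx] <- ifelse(ok, 6 - 2 * ll, Inf)
        r2_v[idx] <- ifelse(ok, 1 - rss / syy_c, NA_real_)
        ok_v[idx] <- ok
      }
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        cu_type = cu_type, temp_stat = stat,
        threshold = rep(ths, each = nL), window = rep(Ls, times = nt),
        a = a_v, b = b_v, sigma = s_v, n_obs = m, log_lik = ll_v,
        aic = aic_v, r_squared = r2_v, converged = ok_v)
    }
  }
  fits <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (!any(fits$converged))
    stop_("every configuration in the grid failed to fit")

  min_aic <- min(fits$aic)
  best_index <- which(fits$aic <= min_aic + tie_tol)[1L]
  tie_report <- fits[fits$aic <= min_aic + tie_tol,
                     c("cu_type", "temp_stat", "threshold", "window", "aic")]
  best_row <- fits[best_index, ]
  best_cfg <- cu_config(best_row$cu_type, best_row$temp_stat,
                        best_row$threshold, best_row$window)
  best <- fit_cu_model(series, observations, best_cfg,
                       aggregation = aggregation, eps = eps)
  structure(list(fits = fits, best = best, best_index = best_index,
                 tie_report = tie_report, spec = spec,
                 aggregation = aggregation, n_obs = m),
            class = "cu_grid_search")
}

#' @export
print.cu_grid_search <- function(x, ...) {
  cat(sprintf("Chilling-unit AIC grid search: %d configurations, %d response points\n",
              nrow(x$fits), x$n_obs))
  cat(sprintf("  failed fits (AIC = +Inf): %d\n", sum(!x$fits$converged)))
  if (nrow(x$tie_report) > 1L)
    cat(sprintf("  AIC ties at the minimum: %d (first in grid order selected)\n",
                nrow(x$tie_report)))
  cat("Selected (minimum AIC):\n")
  print(x$best)
  invisible(x)
}

#' @export
summary.cu_grid_search <- function(object, n_top = 6L, ...) {
  ord <- order(object$fits$aic)
  top <- object$fits[head(ord, n_top),
                     c("cu_type", "temp_stat", "threshold", "window",
                       "aic", "log_lik", "r_squared")]
  structure(list(search = object, top = top), class = "summary.cu_grid_search")
}

#' @export
print.summary.cu_grid_search <- function(x, ...) {
  print(x$search)
  cat("\nBest configurations by AIC:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @method coef cu_grid_search
#' @export
coef.cu_grid_search <- function(object, ...) coef(object$best)

#' @method predict cu_grid_search
#' @export
predict.cu_grid_search <- function(object, ...) predict(object$best, ...)

#' Plot the AIC surface of a grid search
#'
#' Heatmap (with contours) of AIC over threshold x window for one
#' (CU type, temperature statistic) family; defaults to the family of the
#' selected model. Failed fits are blank.
#'
#' @param x a `cu_grid_search`.
#' @param cu_type,temp_stat family to display.
#' @param ... passed to [image()].
#' @method plot cu_grid_search
#' @export
plot.cu_grid_search <- function(x,
                                cu_type = x$best$cu_config$cu_type,
                                temp_stat = x$best$cu_config$temp_stat,
                                ...) {
  f <- x$fits[x$fits$cu_type == cu_type & x$fits$temp_stat == temp_stat, ]
  if (nrow(f) == 0L) stop_("family not present in the searched grid")
  ths <- sort(unique(f$threshold)); Ls <- sort(unique(f$window))
  z <- matrix(NA_real_, length(ths), length(Ls))
  z[cbind(match(f$threshold, ths), match(f$window, Ls))] <-
    ifelse(is.finite(f$aic), f$aic, NA)
  image(ths, Ls, z, col = hcl.colors(64, "viridis", rev = TRUE),
        xlab = "threshold Th (degC)", ylab = "window L (days)",
        main = sprintf("AIC: %s / daily %s", cu_type, temp_stat), ...)
  contour(ths, Ls, z, add = TRUE, col = "grey30")
  if (x$best$cu_config$cu_type == cu_type &&
      x$best$cu_config$temp_stat == temp_stat)
    points(x$best$cu_config$threshold, x$best$cu_config$window,
           pch = 4, cex = 1.5, lwd = 2, col = "red")
  invisible(x)
}
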