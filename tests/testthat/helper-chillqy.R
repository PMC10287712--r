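# Shared fixtures and independent oracles for the test suite.

# A daily_temps series with given tmax (tavg/tmin offset below it) --------
make_series <- function(tmax, start = as.Date("2020-01-01"),
                        site_id = "s1") {
  daily_temps(site_id, start + seq_along(tmax) - 1L,
              tmax = tmax, tmin = tmax - 9, tavg = tmax - 4.5)
}

# Three training seasons of synthetic climate + biweekly QY ---------------
make_training_data <- function(seed = 1L, truth = true_model(),
                               n_seasons = 3L, start_year = 2013L,
                               climate = climate_params()) {
  start <- as.Date(sprintf("%d-08-01", start_year))
  n_days <- as.integer(as.Date(sprintf("%d-04-15",
                                       start_year + n_seasons)) - start) + 1L
  series <- gen_temperature_series(climate, start, n_days, seed = seed)
  obs <- do.call(rbind, lapply(seq_len(n_seasons), function(k) {
    gen_qy_observations(series, truth,
                        first_date = as.Date(sprintf("%d-11-01",
                                                     start_year + k - 1L)),
                        last_date = as.Date(sprintf("%d-03-31",
                                                    start_year + k)),
                        seed = seed * 100L + k)
  }))
  class(obs) <- c("qy_obs", "data.frame")
  list(series = series, obs = obs)
}

# Brute-force CU oracle: literal double loop over (date, window day) ------
brute_cu <- function(series, config, raw_sum = FALSE) {
  x <- switch(config$temp_stat, max = series$tmax, min = series$tmin,
              avg = series$tavg)
  L <- config$window
  n <- length(x)
  vapply(L:n, function(d) {
    acc <- 0
    for (delta in (d - L + 1L):d) {
      if (x[delta] < config$threshold) {
        acc <- acc + switch(config$cu_type,
                            day_count = 1,
                            temperature_sum = if (raw_sum) x[delta]
                                              else config$threshold - x[delta])
      }
    }
    acc
  }, numeric(1))
}

# Brute-force grid search oracle: one lm() per configuration --------------
brute_grid_search <- function(series, obs, spec, eps = 1e-3) {
  grid <- enumerate_grid(spec)
  agg <- stats::aggregate(qy ~ line + date, data = obs, FUN = mean)
  agg <- agg[order(agg$date, agg$line), ]
  y <- logit(agg$qy, eps = eps)
  aics <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- cu_config(grid$cu_type[i], grid$temp_stat[i], grid$threshold[i],
                     grid$window[i])
    cu <- compute_cu(series, cfg, quiet = TRUE)
    x <- cu$value[match(agg$date, cu$date)]
    if (length(unique(x)) < 2L) return(Inf)
    fit <- lm(y ~ x)
    n <- length(y)
    rss <- sum(residuals(fit)^2)
    6 - 2 * (-n / 2 * (log(2 * pi * rss / n) + 1))
  }, numeric(1))
  list(grid = grid, aic = aics, best = which.min(aics))
}

expect_same_series <- function(a, b) {
  expect_equal(a$date, b$date)
  expect_equal(a$tmax, b$tmax)
  expect_equal(a$tmin, b$tmin)
  expect_equal(a$tavg, b$tavg)
}
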