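test_that("logit matches closed forms and round-trips", {
  expect_identical(logit(0.5), 0)
  expect_equal(inv_logit(logit(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(logit(0, eps = 1e-3), log(0.001 / 0.999))
  expect_equal(logit(1, eps = 1e-3), -log(0.001 / 0.999))
  expect_error(logit(-0.1), "0, 1")
  expect_error(logit(1.1), "0, 1")
  expect_error(logit(0.5, eps = 0.6), "eps")
})

test_that("assemble_design averages replicates before the logit transform", {
  s <- make_series(rep(20, 40))
  cu <- compute_cu(s, cu_config("day_count", "max", 25, 5), quiet = TRUE)
  obs <- qy_obs("s1", rep(s$date[10], 3), "lineA", 1:3, c(0.4, 0.5, 0.6))
  d <- assemble_design(cu, obs, aggregation = "per_line_date_mean")
  expect_identical(nrow(d), 1L)
  expect_equal(d$logit_qy, 0)  # mean 0.5 -> logit 0
  d2 <- assemble_design(cu, obs, aggregation = "per_observation")
  expect_identical(nrow(d2), 3L)
  expect_error(assemble_design(cu, obs[0, ]), "empty")
  obs_bad <- qy_obs("s1", s$date[2], "lineA", 1, 0.5)  # before first window
  expect_error(assemble_design(cu, obs_bad), "lacking CU coverage")
})

test_that("noise-free collinear data are interpolated exactly", {
  cu <- c(0, 5, 12, 20, 33, 41)
  fit <- fit_logit_linear(cu, -0.05 * cu + 1)
  expect_equal(fit$a, -0.05, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-10)
})

test_that("AIC equals 6 - 2 logLik and logLik matches the density oracle", {
  cu <- c(1, 4, 7, 13, 22)
  y <- c(0.9, 0.4, 0.1, -0.8, -1.6)
  fit <- fit_logit_linear(cu, y)
  expect_identical(fit$aic, 6 - 2 * fit$log_lik)
  # oracle: Gaussian density evaluated at the OLS residuals with ML variance
  ols <- lm(y ~ cu)
  sigma_ml <- sqrt(sum(residuals(ols)^2) / length(y))
  ll_oracle <- sum(dnorm(residuals(ols), sd = sigma_ml, log = TRUE))
  expect_equal(fit$log_lik, ll_oracle, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), unname(coef(ols)[c(2, 1)]), tolerance = 1e-12)
  # the logLik method feeds the stats::AIC generic with k = 3
  expect_equal(AIC(fit), fit$aic)
  expect_identical(attr(logLik(fit), "df"), 3L)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_logit_linear(c(1, 2), c(0, 1)), "at least 3")
  expect_error(fit_logit_linear(rep(3, 5), rnorm(5)), "unidentifiable")
  expect_error(fit_logit_linear(1:4, rep(0, 3)), "lengths differ")
})

test_that("OLS estimates are unbiased over repeated noisy draws", {
  set.seed(21)
  a <- -0.08; b <- 0.9; sd_ <- 0.3
  cu <- seq(0, 46, length.out = 20)
  est <- replicate(500, {
    coef(fit_logit_linear(cu, a * cu + b + rnorm(20, sd = sd_)))
  })
  se_a <- sd(est["a", ]) / sqrt(500)
  se_b <- sd(est["b", ]) / sqrt(500)
  expect_lt(abs(mean(est["a", ]) - a), 3 * se_a)
  expect_lt(abs(mean(est["b", ]) - b), 3 * se_b)
})

test_that("AIC is invariant to a constant shift of the CU values", {
  set.seed(22)
  cu <- runif(30, 0, 40)
  y <- -0.06 * cu + 0.8 + rnorm(30, sd = 0.2)
  f1 <- fit_logit_linear(cu, y)
  f2 <- fit_logit_linear(cu + 17.5, y)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-9)
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
  expect_equal(f2$b, f1$b - f1$a * 17.5, tolerance = 1e-9)
})

test_that("r_squared lies in [0, 1] for intercept models", {
  set.seed(23)
  for (k in 1:20) {
    cu <- runif(12, 0, 40)
    fit <- fit_logit_linear(cu, rnorm(12))
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("grid search equals the literal brute-force double loop", {
  dat <- make_training_data(seed = 31, n_seasons = 1)
  spec <- grid_spec(threshold_ranges = list(max = c(8, 11)),
                    threshold_step = 0.75, window_range = c(10, 50),
                    window_step = 10, cu_types = "day_count",
                    temp_stats = "max")
  gs <- cu_grid_search(dat$series, dat$obs, spec)
  oracle <- brute_grid_search(impute_missing(dat$series), dat$obs, spec)
  expect_identical(nrow(gs$fits), 25L)
  expect_equal(gs$fits$aic, oracle$aic, tolerance = 1e-9)
  expect_identical(gs$best_index, oracle$best)
  # argmin contract
  expect_equal(gs$best$aic, min(gs$fits$aic))
  expect_equal(gs$fits$aic[gs$best_index], min(gs$fits$aic))
})

test_that("grid search works across both CU types and all statistics", {
  dat <- make_training_data(seed = 32, n_seasons = 1)
  spec <- grid_spec(threshold_ranges = list(max = c(9, 10), min = c(0, 1),
                                            avg = c(4.5, 5.5)),
                    threshold_step = 0.5, window_range = c(20, 46),
                    window_step = 13)
  gs <- cu_grid_search(dat$series, dat$obs, spec)
  oracle <- brute_grid_search(impute_missing(dat$series), dat$obs, spec)
  expect_identical(nrow(gs$fits), 6L * 3L * 3L)
  expect_equal(gs$fits$aic, oracle$aic, tolerance = 1e-9)
  expect_identical(gs$best_index, oracle$best)
})

test_that("failed configurations keep the AIC table rectangular", {
  dat <- make_training_data(seed = 33, n_seasons = 1)
  # thresholds far below any winter temperature never accumulate chill
  spec <- grid_spec(threshold_ranges = list(min = c(-60, -55)),
                    threshold_step = 1, window_range = c(5, 10),
                    window_step = 5, cu_types = "day_count",
                    temp_stats = "min")
  expect_error(cu_grid_search(dat$series, dat$obs, spec), "failed")
  # mixed grid: failed rows carry +Inf AIC, search still selects a fit
  spec2 <- grid_spec(threshold_ranges = list(min = c(-60, 0)),
                     threshold_step = 30, window_range = c(20, 40),
                     window_step = 10, cu_types = "day_count",
                     temp_stats = "min")
  gs <- cu_grid_search(dat$series, dat$obs, spec2)
  expect_identical(nrow(gs$fits), 9L)
  expect_true(any(!gs$fits$converged))
  expect_true(all(gs$fits$aic[!gs$fits$converged] == Inf))
  expect_true(is.finite(gs$best$aic))
})

test_that("model recovery: the generating configuration wins at low noise", {
  picks <- t(sapply(1:3, function(seed) {
    dat <- make_training_data(seed = 40 + seed)
    spec <- grid_spec(threshold_ranges = list(max = c(7, 12)),
                      threshold_step = 0.25, window_range = c(30, 60),
                      window_step = 1, cu_types = "day_count",
                      temp_stats = "max")
    b <- cu_grid_search(dat$series, dat$obs, spec)$best$cu_config
    c(b$threshold, b$window)
  }))
  modal <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  expect_equal(modal(picks[, 1]), 9.5)
  expect_equal(modal(picks[, 2]), 46)
})

test_that("cu_fit methods are coherent", {
  dat <- make_training_data(seed = 51, n_seasons = 1)
  fit <- fit_cu_model(dat$series, dat$obs, true_model()$cu_config)
  expect_named(coef(fit), c("a", "b"))
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_equal(fitted(fit, "logit") + residuals(fit), fit$data$logit_qy)
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) > 0 & unlist(s1) < 1))
  sm <- summary(fit)
  expect_true(all(is.finite(sm$coefficients)))
  expect_output(print(fit), "Logit-linear")
})
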