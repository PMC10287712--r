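make_fit <- function(seed = 61, n = 30, a = -0.08, b = 0.9, sd_ = 0.25) {
  set.seed(seed)
  cu <- runif(n, 0, 46)
  fit_logit_linear(cu, a * cu + b + rnorm(n, sd = sd_))
}

test_that("interval geometry: narrowest at the CU mean, PI contains CI", {
  fit <- make_fit()
  grid <- seq(0, 46, by = 0.5)
  ci <- predict(fit, grid, interval = "confidence", scale = "logit")
  pi_ <- predict(fit, grid, interval = "prediction", scale = "logit")
  width <- ci$upr - ci$lwr
  expect_equal(grid[which.min(width)], grid[which.min(abs(grid - fit$xbar))])
  expect_true(all(pi_$lwr < ci$lwr) && all(pi_$upr > ci$upr))
  # negative slope: predicted QY strictly decreasing in CU
  qy <- predict(fit, grid)
  expect_true(all(diff(qy) < 0))
})

test_that("interval predictions nest and stay inside [0, 1]", {
  fit <- make_fit(62)
  p <- predict_with_intervals(fit, seq(0, 46, by = 1))
  expect_true(all(p$pi_low <= p$ci_low & p$ci_low <= p$qy_hat &
                    p$qy_hat <= p$ci_high & p$ci_high <= p$pi_high))
  expect_true(all(p$pi_low >= 0 & p$pi_high <= 1))
})

test_that("intervals match the lm oracle on the logit scale", {
  fit <- make_fit(63)
  d <- fit$data
  ref <- lm(logit_qy ~ cu, data = d)
  nd <- data.frame(cu = c(0, 11.3, 27, 46))
  for (kind in c("confidence", "prediction")) {
    mine <- predict(fit, nd$cu, interval = kind, scale = "logit")
    theirs <- predict(ref, nd, interval = kind, level = 0.95)
    expect_equal(mine$fit, unname(theirs[, "fit"]), tolerance = 1e-10)
    expect_equal(mine$lwr, unname(theirs[, "lwr"]), tolerance = 1e-10)
    expect_equal(mine$upr, unname(theirs[, "upr"]), tolerance = 1e-10)
  }
})

test_that("coverage counting is inclusive at the interval endpoints", {
  fit <- make_fit(64)
  p <- predict_with_intervals(fit, c(5, 15, 25))
  # observations exactly on a bound count as inside
  res <- coverage_count(p, c(p$ci_low[1], p$ci_high[2], p$qy_hat[3]),
                        "confidence")
  expect_equal(res$n_within, 3)
  expect_equal(res$n_total, 3)
  # all at the prediction: full coverage
  expect_equal(coverage_count(p, p$qy_hat, "prediction")$n_within, 3)
  # matching by date when both sides carry dates
  p2 <- predict_with_intervals(fit, c(5, 15), dates = as.Date("2020-01-01") + 0:1)
  obs <- data.frame(date = as.Date("2020-01-02"), qy = p2$qy_hat[2])
  expect_equal(coverage_count(p2, obs, "confidence")$n_within, 1)
  expect_error(coverage_count(p2, data.frame(date = as.Date("2021-01-01"),
                                             qy = 0.5)),
               "no prediction")
})

test_that("coverage is identical on the logit and QY scales", {
  fit <- make_fit(65)
  cu_new <- runif(40, 0, 46)
  set.seed(66)
  y_new <- fit$a * cu_new + fit$b + rnorm(40, sd = 0.25)
  p <- predict_with_intervals(fit, cu_new)
  n_qy <- coverage_count(p, plogis(y_new), "prediction")$n_within
  lg <- predict(fit, cu_new, interval = "prediction", scale = "logit")
  n_logit <- sum(y_new >= lg$lwr & y_new <= lg$upr)
  expect_identical(n_qy, n_logit)
})

test_that("prediction intervals attain nominal coverage over refit cycles", {
  set.seed(67)
  hits <- replicate(500, {
    cu <- runif(20, 0, 46)
    y <- -0.08 * cu + 0.9 + rnorm(20, sd = 0.3)
    fit <- fit_logit_linear(cu, y)
    x_new <- runif(1, 0, 46)
    y_new <- -0.08 * x_new + 0.9 + rnorm(1, sd = 0.3)
    p <- predict(fit, x_new, interval = "prediction", scale = "logit")
    y_new >= p$lwr && y_new <= p$upr
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("confidence intervals cover the true mean response", {
  set.seed(68)
  x0 <- 20
  truth <- -0.08 * x0 + 0.9
  hits <- replicate(400, {
    cu <- runif(20, 0, 46)
    fit <- fit_logit_linear(cu, -0.08 * cu + 0.9 + rnorm(20, sd = 0.3))
    p <- predict(fit, x0, interval = "confidence", scale = "logit")
    truth >= p$lwr && truth <= p$upr
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("prediction metrics match hand computations", {
  expect_equal(prediction_metrics(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))[
    c("pearson_r", "r_squared_pred")],
    list(pearson_r = 1, r_squared_pred = 1))
  obs <- c(0.1, 0.2, 0.7)
  m <- prediction_metrics(rev(obs), obs)
  # by hand: centred x = (11,-4,-7)/30, y = (-7,-4,11)/30 -> r = -138/186
  expect_equal(m$pearson_r, -23 / 31, tolerance = 1e-12)
  # predicting the observed mean gives exactly zero explained variance
  # constant predictor: zero explained variance (correlation itself is NA)
  m0 <- suppressWarnings(prediction_metrics(rep(mean(obs), 3), obs))
  expect_equal(m0$r_squared_pred, 0)
  # r_squared_pred can be negative and is not clipped
  m_bad <- prediction_metrics(c(0.9, 0.9, 0.1), obs)
  expect_lt(m_bad$r_squared_pred, 0)
  expect_error(prediction_metrics(c(0.1, 0.2, 0.3), rep(0.5, 3)),
               "constant")
})

test_that("season validation reports coverage and fit quality", {
  truth <- true_model()
  dat <- make_training_data(seed = 71)
  fit <- fit_cu_model(dat$series, dat$obs, truth$cu_config)
  hold <- gen_qy_observations(dat$series, truth,
                              first_date = as.Date("2015-11-01"),
                              last_date = as.Date("2016-03-31"), seed = 999)
  v <- validate_season(fit, dat$series, hold, season = "2015-2016",
                       interval_kind = "prediction")
  expect_s3_class(v, "qy_validation")
  expect_identical(v$n_points, 22L)  # 11 dates x 2 lines
  expect_gte(v$n_within, 0L)
  expect_lte(v$n_within, v$n_points)
  expect_gt(v$pearson_r, 0.9)       # low-noise synthetic season
  expect_gt(v$r_squared_pred, 0.8)
  expect_identical(sum(v$table$within), as.integer(v$n_within))
  expect_output(print(v), "within the 95% prediction interval")
})
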