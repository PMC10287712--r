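test_that("missing-rate filter uses an inclusive boundary", {
  tmax <- rnorm(100, 10)
  tmax[1:10] <- NA
  s <- daily_temps("s", as.Date("2020-01-01") + 0:99, tmax, tmax - 9,
                   tmax - 4.5)
  res <- filter_by_missing_rate(s, "max", max_rate = 0.10)
  expect_true(res$accepted)      # 10/100 is exactly at the bound
  expect_equal(res$rate, 0.10)
  tmax[11] <- NA
  s2 <- daily_temps("s", as.Date("2020-01-01") + 0:99, tmax, tmax - 9,
                    tmax - 4.5)
  expect_false(filter_by_missing_rate(s2, "max", 0.10)$accepted)
  s3 <- make_series(rnorm(50, 10))
  res3 <- filter_by_missing_rate(s3, "avg")
  expect_true(res3$accepted)
  expect_equal(res3$rate, 0)
})

test_that("single missing days receive the mean of their neighbours", {
  s <- daily_temps("s", as.Date("2020-01-01") + 0:2, c(5, NA, 7),
                   c(1, NA, 3), c(3, NA, 5))
  out <- impute_missing(s)
  expect_equal(out$tmax, c(5, 6, 7))
  expect_equal(out$tmin, c(1, 2, 3))
})

test_that("imputation is the identity on complete series", {
  s <- make_series(c(4, 5, 6, 7))
  expect_same_series(impute_missing(s), s)
})

test_that("runs of missing days are linearly interpolated", {
  s <- daily_temps("s", as.Date("2020-01-01") + 0:3, c(4, NA, NA, 10),
                   c(0, NA, NA, 6), c(2, NA, NA, 8))
  expect_equal(impute_missing(s)$tmax, c(4, 6, 8, 10))
})

test_that("imputation preserves non-missing values exactly", {
  set.seed(31)
  tmax <- rnorm(60, 8, 4)
  miss <- sample(2:59, 12)
  tm <- tmax; tm[miss] <- NA
  s <- daily_temps("s", as.Date("2020-01-01") + 0:59, tm, tm - 9, tm - 4.5)
  out <- impute_missing(s)
  expect_equal(out$tmax[-miss], tmax[-miss])
  expect_false(anyNA(out$tmax))
})

test_that("a missing boundary day is rejected naming the date", {
  s <- daily_temps("s", as.Date("2020-01-01") + 0:2, c(NA, 5, 7),
                   c(NA, 1, 3), c(NA, 3, 5))
  expect_error(impute_missing(s), "2020-01-01")
  s2 <- daily_temps("s", as.Date("2020-01-01") + 0:2, c(5, 6, NA),
                    c(1, 2, NA), c(3, 4, NA))
  expect_error(impute_missing(s2), "2020-01-03")
})

test_that("compute_cu matches hand-worked examples", {
  s <- make_series(c(10, 9, 8, 10, 9))
  dc <- compute_cu(s, cu_config("day_count", "max", 9.5, 5), quiet = TRUE)
  expect_equal(dc$value, 3)  # days with tmax < 9.5: 9, 8, 9
  expect_equal(dc$date, s$date[5])

  # threshold below every temperature: both CU types are zero
  s_warm <- make_series(rep(20, 10))
  expect_equal(compute_cu(s_warm, cu_config("day_count", "max", 0, 4),
                          quiet = TRUE)$value, rep(0, 7))
  expect_equal(compute_cu(s_warm, cu_config("temperature_sum", "max", 0, 4),
                          quiet = TRUE)$value, rep(0, 7))

  # temperature deficit sum: tavg [5, 6], Th = 7, L = 2 -> (7-5)+(7-6) = 3
  s2 <- daily_temps("s", as.Date("2020-01-01") + 0:1, c(12, 13), c(1, 2),
                    c(5, 6))
  ts <- compute_cu(s2, cu_config("temperature_sum", "avg", 7, 2),
                   quiet = TRUE)
  expect_equal(ts$value, 3)
})

test_that("compute_cu equals the brute-force double loop on random series", {
  set.seed(11)
  for (rep_ in 1:25) {
    n <- sample(15:40, 1)
    s <- make_series(rnorm(n, mean = 8, sd = 6))
    cfg <- cu_config(sample(c("day_count", "temperature_sum"), 1),
                     sample(c("max", "min", "avg"), 1),
                     threshold = runif(1, -5, 12),
                     window = sample(1:8, 1))
    expect_equal(compute_cu(s, cfg, quiet = TRUE)$value, brute_cu(s, cfg))
    if (cfg$cu_type == "temperature_sum")
      expect_equal(compute_cu(s, cfg, raw_sum = TRUE, quiet = TRUE)$value,
                   brute_cu(s, cfg, raw_sum = TRUE))
  }
})

test_that("CU values are monotone in threshold and window", {
  set.seed(12)
  s <- make_series(rnorm(80, 8, 5))
  for (type in c("day_count", "temperature_sum")) {
    v1 <- compute_cu(s, cu_config(type, "avg", 4, 10), quiet = TRUE)$value
    v2 <- compute_cu(s, cu_config(type, "avg", 7, 10), quiet = TRUE)$value
    expect_true(all(v2 >= v1))
    w1 <- compute_cu(s, cu_config(type, "avg", 4, 5), quiet = TRUE)
    w2 <- compute_cu(s, cu_config(type, "avg", 4, 15), quiet = TRUE)
    shared <- match(w2$date, w1$date)  # longer window covers fewer dates
    expect_true(all(w2$value >= w1$value[shared]))
  }
  # day counts are integers bounded by the window
  v <- compute_cu(s, cu_config("day_count", "min", 2, 7), quiet = TRUE)$value
  expect_true(all(v == round(v) & v >= 0 & v <= 7))
})

test_that("day counts are translation equivariant", {
  set.seed(13)
  tmax <- rnorm(50, 8, 5)
  s <- make_series(tmax)
  s_shift <- make_series(tmax + 3.25)
  a <- compute_cu(s, cu_config("day_count", "max", 6, 9), quiet = TRUE)
  b <- compute_cu(s_shift, cu_config("day_count", "max", 9.25, 9),
                  quiet = TRUE)
  expect_equal(a$value, b$value)
})

test_that("compute_cu requires imputed input and enough history", {
  s <- daily_temps("s", as.Date("2020-01-01") + 0:2, c(5, NA, 7),
                   c(1, NA, 3), c(3, NA, 5))
  expect_error(compute_cu(s, cu_config("day_count", "max", 9, 2)),
               "impute")
  expect_error(compute_cu(make_series(c(5, 6)),
                          cu_config("day_count", "max", 9, 5)),
               "insufficient history")
  expect_message(compute_cu(make_series(rnorm(10, 8)),
                            cu_config("day_count", "max", 9, 3)),
                 "dropping 2 leading")
})

test_that("period_max_cu extracts the maximum over the period", {
  s <- make_series(rep(20, 10))
  cu <- compute_cu(s, cu_config("day_count", "max", 25, 3), quiet = TRUE)
  cu$value <- c(0, 3, 35, 12, 7, 1, 0, 2)
  expect_equal(period_max_cu(cu), 35)
  expect_equal(period_max_cu(cu, start = cu$date[4]), 12)
  expect_error(period_max_cu(cu, start = cu$date[8] + 5), "overlap")
  # constant series
  cu$value <- rep(7, 8)
  expect_equal(period_max_cu(cu), 7)
})

test_that("the default grid enumerates 61 x 70 configurations per pair", {
  one_pair <- grid_spec(cu_types = "day_count", temp_stats = "max")
  expect_identical(nrow(enumerate_grid(one_pair)), 61L * 70L)
  full <- enumerate_grid(grid_spec())
  expect_identical(nrow(full), 25620L)
  # deterministic ordering: threshold ascending then window ascending
  blk <- full[full$cu_type == "day_count" & full$temp_stat == "max", ]
  expect_true(!is.unsorted(blk$threshold))
  expect_equal(blk$window[1:70], 1:70)
})

test_that("collapsed grids and invalid steps behave as specified", {
  tiny <- grid_spec(threshold_ranges = list(max = c(5, 5), min = c(0, 0),
                                            avg = c(2, 2)),
                    window_range = c(1, 1))
  expect_identical(nrow(enumerate_grid(tiny)), 6L)
  expect_error(grid_spec(threshold_ranges = list(max = c(0, 1), min = c(-7, 8),
                                                 avg = c(-2.5, 12.5)),
                         threshold_step = 0.3),
               "does not divide")
  expect_error(grid_spec(window_range = c(1, 10), window_step = 4),
               "does not divide")
})
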