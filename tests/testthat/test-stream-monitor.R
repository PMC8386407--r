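cfg <- monitor_config()

test_that("monitor config enforces its invariants", {
  expect_error(monitor_config(outlier_k = 0), "outlier_k")
  expect_error(monitor_config(window_days = 2), "window_days")
  expect_error(monitor_config(alpha = 1), "alpha")
  expect_error(baseline_norm(0, 0, 30), "variance")
})

test_that("a constant baseline is rejected as degenerate", {
  d <- study_start + 0:40
  expect_error(fit_baseline(d, rep(5, 41), cfg), "zero variance")
})

test_that("insufficient baseline data names required vs available days", {
  d <- study_start + 0:40
  v <- rnorm(41)
  v[1:25] <- NA
  expect_error(fit_baseline(d, v, cfg), "5 day\\(s\\) available, 21 required")
})

test_that("a sleep-onset baseline clustered at 20:00 averages to 20:00", {
  set.seed(30)
  d <- study_start + 0:29
  v <- (1200 + rnorm(30, sd = 20)) %% 1440
  nm <- fit_baseline(d, v, cfg, scale_type = "circular_minutes")
  expect_equal(nm$mean, 1200, tolerance = 0.02)
  expect_gt(nm$variance, 0)
})

test_that("the baseline mean of an i.i.d. Gaussian stream concentrates", {
  means <- sapply(1:50, function(s) {
    v <- withr::with_seed(s, rnorm(30))
    fit_baseline(study_start + 0:29, v, cfg)$mean
  })
  expect_true(mean(abs(means) <= 3 / sqrt(30)) > 0.95)
})

test_that("point outliers fire beyond k baseline SDs and not within", {
  nm <- baseline_norm(1000, 100^2, 30,
                      interval = c(study_start - 1, study_start + 29))
  d <- study_start + 30:32
  a <- detect_point_outliers(d, c(1300, 1200, 950), nm, cfg)
  expect_equal(nrow(a), 1)
  expect_equal(a$statistic, 3)
  expect_equal(a$direction, 1)
  expect_equal(a$date, d[1]) # |z| = 2 and 0.5 stay quiet
})

test_that("alerts are only ever emitted after the baseline interval", {
  set.seed(31)
  d <- study_start + 0:99
  v <- rnorm(100)
  v[5] <- 10 # a wild value inside the baseline window
  nm <- baseline_norm(0, 1, 30, interval = c(study_start - 1,
                                             study_start + 29))
  a <- detect_point_outliers(d, v, nm, cfg)
  expect_true(all(a$date > study_start + 29))
  ws <- moving_window_stats(d, v, nm, cfg)
  expect_true(all(ws$date > study_start + 29))
})

test_that("moving-window stats equal brute-force recomputation", {
  set.seed(32)
  d <- study_start + sort(sample(0:89, 70))
  v <- rnorm(70, 50, 8)
  nm <- fit_baseline(d, v, cfg)
  ws <- moving_window_stats(d, v, nm, cfg)
  for (i in sample(nrow(ws), 10)) {
    day <- ws$date[i]
    inw <- d > day - 14 & d <= day
    expect_equal(ws$mean[i], mean(v[inw]), tolerance = 1e-10)
    expect_equal(ws$variance[i], var(v[inw]), tolerance = 1e-8)
    expect_equal(ws$n[i], sum(inw))
  }
  # a day with under half the window covered is a gap
  sparse_d <- study_start + c(0:29, seq(30, 80, by = 3))
  sparse_v <- rnorm(length(sparse_d))
  nm2 <- fit_baseline(sparse_d, sparse_v, cfg)
  ws2 <- moving_window_stats(sparse_d, sparse_v, nm2, cfg)
  expect_true(all(ws2$n >= 7))
  expect_lt(nrow(ws2), 51)
})

test_that("a constant post-baseline stream has zero moving variance", {
  set.seed(33)
  v <- c(rnorm(30), rep(5, 40))
  d <- study_start + 0:69
  nm <- fit_baseline(d, v, cfg)
  ws <- moving_window_stats(d, v, nm, cfg)
  tailw <- ws[ws$date >= study_start + 45, ]
  expect_true(all(tailw$variance == 0))
  expect_true(all(tailw$mean == 5))
  # zero-variance window: flagged as a degenerate downward shift, no crash
  vs <- test_variance_shift(ws, nm, cfg)
  expect_true(all(vs$flagged[vs$date >= study_start + 45]))
  expect_true(all(vs$direction[vs$date >= study_start + 45] == -1))
})

test_that("a +2 SD mean step is flagged within the window length", {
  set.seed(34)
  d <- study_start + 0:58
  v <- c(rnorm(30), rnorm(29) + 2)
  nm <- fit_baseline(d, v, cfg)
  ws <- moving_window_stats(d, v, nm, cfg)
  ms <- test_mean_shift(ws, nm, cfg)
  hit <- ms$flagged & ms$date <= study_start + 29 + 14
  expect_true(any(hit))
  expect_true(all(ms$direction[hit] == 1))
})

test_that("without a shift the daily mean-flag rate stays near alpha", {
  rates <- sapply(1:30, function(s) {
    v <- withr::with_seed(1000 + s, rnorm(120))
    d <- study_start + 0:119
    nm <- fit_baseline(d, v, cfg)
    ws <- moving_window_stats(d, v, nm, cfg)
    mean(test_mean_shift(ws, nm, cfg)$flagged)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})

test_that("a quadrupled variance is flagged while equal variance is not", {
  set.seed(35)
  d <- study_start + 0:57
  v <- c(rnorm(30), rnorm(28) * 2)
  nm <- fit_baseline(d, v, cfg)
  vs <- test_variance_shift(moving_window_stats(d, v, nm, cfg), nm, cfg)
  expect_true(any(vs$flagged & vs$direction == 1))
  rates <- sapply(1:30, function(s) {
    v <- withr::with_seed(2000 + s, rnorm(120))
    d <- study_start + 0:119
    nm <- fit_baseline(d, v, cfg)
    mean(test_variance_shift(moving_window_stats(d, v, nm, cfg),
                             nm, cfg)$flagged)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.04)
})

test_that("a noiseless ramp saturates the slope statistic", {
  set.seed(36)
  v <- c(rnorm(30, sd = 1), 100 + 5 * (1:30))
  d <- study_start + 0:59
  nm <- fit_baseline(d, v, cfg)
  sl <- test_slope_change(d, v, nm, cfg)
  late <- sl[sl$date >= study_start + 45, ]
  expect_true(all(late$flagged))
  expect_true(all(abs(late$statistic) > 1e3))
})

test_that("white noise keeps the slope flag rate near alpha", {
  rates <- sapply(1:30, function(s) {
    v <- withr::with_seed(3000 + s, rnorm(120))
    d <- study_start + 0:119
    nm <- fit_baseline(d, v, cfg)
    mean(test_slope_change(d, v, nm, cfg)$flagged)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})

test_that("slope flags precede point outliers under a slow drift", {
  set.seed(37)
  base <- rnorm(30, 1200, 20)
  drift <- 1200 - 15 / 7 * (1:42) + rnorm(42, sd = 20) # -15 min/week
  v <- (c(base, drift)) %% 1440
  d <- study_start + 0:71
  nm <- fit_baseline(d, v, cfg, scale_type = "circular_minutes")
  sl <- test_slope_change(d, v, nm, cfg)
  po <- detect_point_outliers(d, v, nm, cfg)
  first_slope <- suppressWarnings(min(sl$date[sl$flagged]))
  first_point <- suppressWarnings(min(po$date))
  expect_true(is.finite(as.numeric(first_slope)))
  expect_true(first_slope < first_point || nrow(po) == 0)
})

test_that("a drift across midnight is detected like the same drift midday", {
  set.seed(38)
  noise <- rnorm(72, sd = 15)
  shape <- c(rep(0, 30), seq(0, 90, length.out = 42)) # +90 min drift
  mk <- function(center) (center + shape + noise) %% 1440
  run <- function(center) {
    v <- mk(center)
    d <- study_start + 0:71
    nm <- fit_baseline(d, v, cfg, scale_type = "circular_minutes")
    list(
      ms = test_mean_shift(moving_window_stats(d, v, nm, cfg), nm, cfg),
      sl = test_slope_change(d, v, nm, cfg)
    )
  }
  near_midnight <- run(23.5 * 60) # crosses 00:00 during the drift
  midday <- run(720)
  expect_equal(near_midnight$ms$flagged, midday$ms$flagged)
  expect_equal(near_midnight$ms$statistic, midday$ms$statistic,
               tolerance = 1e-8)
  expect_equal(near_midnight$sl$flagged, midday$sl$flagged)
})

test_that("no alert at day d uses any sample after d", {
  set.seed(39)
  d <- study_start + 0:99
  v <- rnorm(100)
  nm <- fit_baseline(d, v, cfg)
  cut <- study_start + 70
  full <- test_mean_shift(moving_window_stats(d, v, nm, cfg), nm, cfg)
  trunc <- test_mean_shift(
    moving_window_stats(d[d <= cut], v[d <= cut], nm, cfg), nm, cfg
  )
  keep <- full$date <= cut
  expect_equal(full$flagged[keep], trunc$flagged)
  expect_equal(full$statistic[keep], trunc$statistic)
  sf <- test_slope_change(d, v, nm, cfg)
  st <- test_slope_change(d[d <= cut], v[d <= cut], nm, cfg)
  expect_equal(sf$statistic[sf$date <= cut], st$statistic)
})

test_that("monitor_patient unions alert kinds and lists skipped metrics", {
  co <- small_cohort()
  m <- co$metrics[co$metrics$patient_id == "P001", ]
  mon <- monitor_patient(m, cfg, start_date = study_start)
  expect_s3_class(mon, "psymon_monitor")
  # weekly/bidaily surveys cannot reach 21 baseline days and are skipped
  expect_true(all(c("weekly_summary", "bidaily_summary") %in%
                    mon$skipped$metric))
  expect_true(all(mon$alerts$kind %in%
                    c("point_outlier", "mean_shift", "variance_shift",
                      "slope_change")))
  expect_true(all(mon$alerts$date > study_start + 29))
  g <- glance(mon)
  expect_equal(g$patient_id, "P001")
  expect_identical(tidy(mon), mon$alerts)
})

test_that("a patient with no post-baseline data yields no alerts, no error", {
  m <- make_stream(rnorm(30, 420, 20))
  mon <- monitor_patient(m, cfg, start_date = study_start)
  expect_equal(nrow(mon$alerts), 0)
})

test_that("the monitor plot assembles the three-panel layout", {
  co <- small_cohort()
  m <- co$metrics[co$metrics$patient_id == "P001", ]
  mon <- monitor_patient(m, cfg, start_date = study_start)
  p <- ggplot2::autoplot(mon, "sleep_start_time")
  expect_s3_class(p, "ggplot")
  expect_error(ggplot2::autoplot(mon, "no_such_metric"), "not among")
})
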