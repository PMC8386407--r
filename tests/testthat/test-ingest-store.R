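test_that("metric streams round-trip through CSV for every scale type", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(co$metrics, path)
  back <- read_metrics(path)
  expect_identical(back, co$metrics)
  # all four scale types were actually exercised
  expect_setequal(unique(co$metrics$scale_type),
                  c("linear", "count", "circular_minutes", "ordinal"))
})

test_that("visits round-trip through CSV", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_visits(co$visits, path)
  expect_equal(as.data.frame(read_visits(path)),
               as.data.frame(co$visits))
})

test_that("malformed clock times are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,metric,period,date,value",
    "P001,sleep_start_time,nightly,2015-08-08,22:30",
    "P001,sleep_start_time,nightly,2015-08-09,25:00"
  ), path)
  expect_error(read_metrics(path), "clock time.*line.*3")
})

test_that("duplicate patient/metric/date rows are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,metric,period,date,value",
    "P001,total_steps,daily,2015-08-08,5000",
    "P001,total_steps,daily,2015-08-09,6000",
    "P001,total_steps,daily,2015-08-08,7000"
  ), path)
  expect_error(read_metrics(path), "duplicate.*lines 2, 4")
})

test_that("unknown metrics are rejected unless explicitly allowed", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,metric,period,date,value",
    "P001,heart_rate,daily,2015-08-08,62"
  ), path)
  expect_error(read_metrics(path), "unknown metric.*heart_rate")
  ok <- read_metrics(path, allow_unknown = TRUE)
  expect_equal(ok$source, "unknown")
  expect_equal(ok$value, 62)
})

test_that("visit validation enforces item/total consistency", {
  v <- make_visit()
  v$panss_total <- v$panss_total + 1
  path <- withr::local_tempfile(fileext = ".csv")
  write_visits(v, path)
  expect_error(read_visits(path), "PANSS total")
})

test_that("one positive item at 5 triggers the relapse flag", {
  v <- make_visit(p = c(5, 1, 1, 1, 1, 1, 1))
  expect_true(flag_relapse(v)$relapse_flag)
})

test_that("a single negative item at 5 does not trigger, two do", {
  v1 <- make_visit(p = rep(4, 7), n = c(5, 4, 4, 4, 4, 4, 4))
  expect_false(flag_relapse(v1)$relapse_flag)
  v2 <- make_visit(p = rep(4, 7), n = c(5, 5, 4, 4, 4, 4, 4))
  expect_true(flag_relapse(v2)$relapse_flag)
})

test_that("a total increase requiring medication change triggers the flag", {
  v <- make_visit(p = rep(4, 7), n = rep(4, 7), med_change = TRUE)
  expect_true(flag_relapse(v, total_increased = TRUE)$relapse_flag)
  expect_false(flag_relapse(v, total_increased = FALSE)$relapse_flag)
  v2 <- make_visit(p = rep(4, 7), n = rep(4, 7), med_change = FALSE)
  expect_false(flag_relapse(v2, total_increased = TRUE)$relapse_flag)
})

test_that("items of 4 everywhere never flag (boundary below 5)", {
  v <- make_visit(p = rep(4, 7), n = rep(4, 7), g = rep(4, 16))
  expect_false(flag_relapse(v)$relapse_flag)
})

test_that("missing PANSS items are an error, not silently imputed", {
  v <- make_visit()
  v$panss_p3 <- NA_real_
  expect_error(flag_relapse(v), "missing")
  expect_error(flag_relapse(v[, setdiff(names(v), "panss_n2")]),
               "panss_n2")
})

test_that("full wear gives 100% coverage and compliance", {
  cfg <- sim_config(n_patients = 2, observation_days = 28, seed = 2,
                    wear_prob = 1, survey_response_prob = 1)
  co <- simulate_cohort(cfg)
  rep <- compute_compliance(co$metrics, study_start - 1, study_start + 27,
                            start_date = study_start)
  expect_equal(rep$streams$data_coverage, rep(1, 4))
  expect_equal(rep$streams$device_compliance, rep(1, 4))
  expect_true(all(rep$patient_days$compliant))
})

test_that("a device-day worn under half of 24 hours is non-compliant", {
  m <- make_stream(rnorm(10, 420, 10))
  wear <- tibble::tibble(
    patient_id = "P001", source = "actigraph",
    date = study_start + 0:9,
    wear_minutes = c(11 * 60, rep(20 * 60, 9))
  )
  rep <- compute_compliance(m, study_start - 1, study_start + 9,
                            wear = wear, start_date = study_start)
  s <- rep$streams[rep$streams$stream == "actigraph", ]
  expect_equal(s$data_coverage, 1)
  expect_equal(s$device_compliance, 0.9) # the 11 h day fails 11/24 < 0.5
})

test_that("hand-counted fixture: 8 of 10 worn days give 80% / 80%", {
  m <- make_stream(rnorm(8, 420, 10))
  m$date <- study_start + c(0:3, 6:9) # absent on days 5 and 6
  wear <- tibble::tibble(
    patient_id = "P001", source = "actigraph", date = m$date,
    wear_minutes = 13 * 60
  )
  rep <- compute_compliance(m, study_start - 1, study_start + 9,
                            wear = wear, start_date = study_start)
  s <- rep$streams[rep$streams$stream == "actigraph", ]
  expect_equal(s$data_coverage, 0.8)
  expect_equal(s$device_compliance, 0.8)
})

test_that("coverage and compliance never increase when samples are deleted", {
  co <- small_cohort()
  full <- compute_compliance(co$metrics, study_start - 1, study_start + 59,
                             start_date = study_start)
  for (p in c(0.8, 0.5, 0.2)) {
    thinned <- apply_missingness(co$metrics, p, seed = 7, response_prob = p)
    part <- compute_compliance(thinned, study_start - 1, study_start + 59,
                               start_date = study_start)
    expect_true(all(part$streams$data_coverage <=
                      full$streams$data_coverage + 1e-12))
    expect_true(all(part$streams$device_compliance <=
                      full$streams$device_compliance + 1e-12))
    full <- part
  }
})

test_that("a window with no data warns and returns an empty report", {
  m <- make_stream(rnorm(5, 400, 10))
  expect_warning(
    rep <- compute_compliance(m, study_start + 100, study_start + 110,
                              start_date = study_start),
    "no data"
  )
  expect_equal(rep$streams$days_with_data, rep(0L, 4))
})

test_that("a simulated cohort with gaps lands near the configured rates", {
  cfg <- sim_config(n_patients = 10, observation_days = 120, seed = 6)
  co <- simulate_cohort(cfg)
  rep <- compute_compliance(co$metrics, study_start - 1, study_start + 119,
                            start_date = study_start)
  dev <- rep$streams[rep$streams$stream %in% c("actigraph", "garmin"), ]
  expect_true(all(abs(dev$data_coverage - 0.94) < 0.03))
  srv <- rep$streams[grepl("survey", rep$streams$stream), ]
  expect_true(all(abs(srv$data_coverage - 0.85) < 0.05))
})
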