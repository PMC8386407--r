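test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_patients = 2, observation_days = 40, seed = 33)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("every registry metric is present at its stated frequency", {
  cfg <- sim_config(n_patients = 2, observation_days = 56, seed = 5,
                    wear_prob = 1, survey_response_prob = 1)
  co <- simulate_cohort(cfg)
  reg <- metric_registry()
  counts <- dplyr::count(co$metrics, patient_id, metric, period)
  expected <- c(daily = 56, nightly = 56, bidaily = 28, weekly = 8)
  for (r in seq_len(nrow(reg))) {
    got <- counts$n[counts$metric == reg$metric[r] &
                      counts$period == reg$period[r]]
    expect_length(got, 2)
    expect_true(all(got == expected[[reg$period[r]]]),
                label = paste(reg$metric[r], reg$period[r]))
  }
  # visit cadences: biweekly symptom scales, 4-weekly others
  v <- co$visits
  expect_equal(sum(!is.na(v$panss_total)), 2 * 4)
  expect_equal(sum(!is.na(v$psqi_global)), 2 * 2)
})

test_that("non-PSD cross_corr is rejected naming the offending eigenvalue", {
  cc <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  nm <- c("bprs_total", "cds_total", "ymrs_total")
  dimnames(cc) <- list(nm, nm)
  expect_error(sim_config(n_patients = 5, cross_corr = cc),
               "positive semidefinite.*eigenvalue")
})

test_that("cross_corr must be named, symmetric, unit-diagonal", {
  cc <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_error(sim_config(n_patients = 5, cross_corr = cc), "names")
  dimnames(cc) <- list(c("a", "b"), c("a", "b"))
  cc2 <- cc; cc2[1, 2] <- 0.4
  expect_error(sim_config(n_patients = 5, cross_corr = cc2), "symmetric")
  cc3 <- cc; diag(cc3) <- 2
  expect_error(sim_config(n_patients = 5, cross_corr = cc3),
               "\\[-1, 1\\]|diagonal")
})

test_that("the truth record stores the generative ICC and metadata", {
  cfg <- sim_config(n_patients = 2, observation_days = 40, seed = 1,
                    latent_trait_sd = sqrt(3), residual_sd = 1)
  co <- simulate_cohort(cfg)
  expect_equal(co$truth$icc, 0.75)
  expect_match(co$truth$generator_note, "stand-ins")
})

test_that("generated clinical scores respect instrument ranges and sums", {
  co <- small_cohort()
  v <- co$visits
  items <- as.matrix(v[, c(paste0("panss_p", 1:7), paste0("panss_n", 1:7),
                           paste0("panss_g", 1:16))])
  has <- !is.na(v$panss_total)
  expect_true(all(items[has, ] >= 1 & items[has, ] <= 7))
  expect_equal(v$panss_total[has], rowSums(items[has, , drop = FALSE]))
  hasq <- !is.na(v$psqi_global)
  comps <- as.matrix(v[, paste0("psqi_c", 1:7)])
  expect_true(all(comps[hasq, ] >= 0 & comps[hasq, ] <= 3))
  expect_equal(v$psqi_global[hasq], rowSums(comps[hasq, , drop = FALSE]))
  expect_true(all(v$cgi_s[!is.na(v$cgi_s)] %in% 1:7))
  circ <- co$metrics$value[co$metrics$scale_type == "circular_minutes"]
  expect_true(all(circ >= 0 & circ < 1440))
  cnt <- co$metrics$value[co$metrics$scale_type == "count"]
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
})

test_that("relapse injection leaves all pre-onset samples untouched", {
  base_cfg <- sim_config(n_patients = 3, observation_days = 80, seed = 12,
                         wear_prob = 1, survey_response_prob = 1)
  spec <- relapse_spec("P002", onset_day = 40,
                       sleep_onset_drift_min_per_week = -30,
                       activity_variance_multiplier = 3,
                       survey_spike_items = "feel_suspicious")
  cfg2 <- sim_config(n_patients = 3, observation_days = 80, seed = 12,
                     wear_prob = 1, survey_response_prob = 1,
                     relapse = spec)
  plain <- simulate_cohort(base_cfg)
  injected <- simulate_cohort(cfg2)
  onset_date <- study_start + 39
  pre <- function(m) dplyr::arrange(
    m[m$date < onset_date, ],
    patient_id, source, period, metric, date
  )
  expect_identical(pre(plain$metrics), pre(injected$metrics))
  expect_identical(plain$visits[plain$visits$date < onset_date, ],
                   injected$visits[injected$visits$date < onset_date, ])
  # post-onset sleep start really drifts, steps really spread
  post_sleep <- function(co, pid) {
    m <- co$metrics
    m$value[m$patient_id == pid & m$metric == "sleep_start_time" &
              m$date >= onset_date + 21]
  }
  d_inj <- circular_mean_minutes(post_sleep(injected, "P002"))
  d_pl <- circular_mean_minutes(post_sleep(plain, "P002"))
  earlier_by <- (d_pl - d_inj) %% 1440 # -30 min/week from week 3 on
  expect_gt(earlier_by, 60)
  expect_lt(earlier_by, 300)
})

test_that("an identity relapse spec modifies nothing", {
  co <- small_cohort()
  spec <- relapse_spec("P001", onset_day = 30,
                       sleep_onset_drift_min_per_week = 0,
                       activity_variance_multiplier = 1,
                       survey_spike_items = character(),
                       panss_positive_item_target = NULL)
  out <- inject_relapse(co$metrics, co$visits, spec,
                        start_date = study_start)
  expect_identical(out$metrics, co$metrics)
  expect_identical(out$visits, co$visits)
})

test_that("injection into an unknown patient lists the valid ids", {
  co <- small_cohort()
  spec <- relapse_spec("P099", onset_day = 30)
  expect_error(inject_relapse(co$metrics, co$visits, spec,
                              start_date = study_start),
               "P099.*valid ids.*P001")
})

test_that("sleep-onset drift reaches the configured 2-week average", {
  # baseline 20:00 sharp; -15 min/week for 7 weeks; the trailing 2-week
  # window centred on week 6 averages ~90 minutes earlier, i.e. 18:30
  n_days <- 100
  m <- make_stream(rep(1200, n_days), metric = "sleep_start_time",
                   scale_type = "circular_minutes")
  spec <- relapse_spec("P001", onset_day = 51,
                       sleep_onset_drift_min_per_week = -15,
                       activity_variance_multiplier = 1,
                       panss_positive_item_target = NULL)
  out <- inject_relapse(m, small_cohort()$visits[0, ], spec,
                        start_date = study_start)
  last2 <- out$metrics[out$metrics$date > study_start + 99 - 14, ]
  expect_equal(circular_mean_minutes(last2$value), 18.5 * 60, tolerance = 0.01)
})

test_that("injected PANSS manipulation makes the relapse flag fire", {
  cfg <- sim_config(
    n_patients = 4, observation_days = 80, seed = 77,
    relapse = relapse_spec("P003", onset_day = 35,
                           panss_positive_item_target = 5)
  )
  co <- simulate_cohort(cfg)
  v <- co$visits[!is.na(co$visits$panss_total), ]
  flags <- flag_relapse(v)
  first_post <- v$date[v$patient_id == "P003" &
                         v$date >= study_start + 34][1]
  expect_true(flags$relapse_flag[flags$patient_id == "P003" &
                                   flags$date == first_post])
})

test_that("wear_prob = 1 removes nothing and wear_prob = 0 empties devices", {
  co <- small_cohort()
  expect_identical(apply_missingness(co$metrics, 1, seed = 1), co$metrics)
  gone <- apply_missingness(co$metrics, 0, seed = 1, response_prob = 1)
  expect_equal(nrow(gone[gone$source != "survey", ]), 0)
  expect_gt(nrow(gone[gone$source == "survey", ]), 0)
})

test_that("retained device-day fraction matches the binomial law", {
  cfg <- sim_config(n_patients = 25, observation_days = 100, seed = 3,
                    channels = c("total_steps", "sleep_efficiency"),
                    wear_prob = 1, survey_response_prob = 1)
  co <- simulate_cohort(cfg)
  dropped <- apply_missingness(co$metrics, 0.9, seed = 42)
  dev_days <- function(m) nrow(dplyr::distinct(
    m[m$source != "survey", ], patient_id, source, date
  ))
  n0 <- dev_days(co$metrics) # 25 patients x 100 days x 2 devices = 5000
  expect_gte(n0, 5000)
  frac <- dev_days(dropped) / n0
  ci <- qnorm(0.995) * sqrt(0.9 * 0.1 / n0)
  expect_lt(abs(frac - 0.9), ci + 0.01)
})

test_that("circular channels near midnight have no linear-mean artifact", {
  cfg <- sim_config(n_patients = 1, observation_days = 60, seed = 8,
                    channels = "sleep_start_time", wear_prob = 1)
  co <- simulate_cohort(cfg)
  x <- co$metrics$value[co$metrics$metric == "sleep_start_time"]
  m <- circular_mean_minutes(x)
  # default sleep start is 23:00 +/- noise: the circular mean stays near
  # 23:00 even though many raw values wrap past midnight
  expect_true(min(abs(m - 1380), 1440 - abs(m - 1380)) < 120)
  expect_true(any(x < 720) && any(x > 720)) # values straddle midnight
})
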