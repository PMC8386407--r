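#' Vocabulary of device and survey metrics
#'
#' The monitoring study tracks a fixed vocabulary of daily/nightly wrist
#' actigraphy summaries (Philips Actiwatch), daily fitness-band activity
#' summaries (Garmin vivofit) and bidaily/weekly smartphone symptom survey
#' items. Each metric has a source, a sampling period and a scale type that
#' determines how it is aggregated and monitored:
#'
#' * `linear` — ordinary real-valued summaries (minutes, percentages, indices),
#' * `count`  — non-negative integers (steps, activity counts, wake bouts),
#' * `circular_minutes` — clock times stored as minutes after midnight in
#'   `[0, 1440)` and analysed with circular statistics,
#' * `ordinal` — 0–4 symptom survey items.
#'
#' The `mu`/`disp` columns are the location and dispersion used by the
#' synthetic cohort generator on the metric's natural scale (for `count`
#' metrics `disp` is a log-scale SD).
#'
#' @return A tibble with columns `metric`, `source`, `period`, `scale_type`,
#'   `mu`, `disp`. A metric name may appear once per period (several
#'   actigraphy summaries exist in both daily and nightly form), so series
#'   are keyed by `(patient_id, metric, period)`.
#' @examples
#' metric_registry()
#' @export
metric_registry <- function() {
  tribble_ <- function(...) {
    x <- list(...)
    m <- matrix(x, ncol = 6, byrow = TRUE)
    tibble(
      metric = unlist(m[, 1]), source = unlist(m[, 2]), period = unlist(m[, 3]),
      scale_type = unlist(m[, 4]), mu = unlist(m[, 5]), disp = unlist(m[, 6])
    )
  }
  tribble_(
    # Philips Actiwatch, daily summaries
    "time_sedentary_min",        "actigraph", "daily",   "linear", 600,   60,
    "time_low_intensity_min",    "actigraph", "daily",   "linear", 240,   40,
    "time_moderate_intensity_min", "actigraph", "daily", "linear",  45,   15,
    "time_vigorous_intensity_min", "actigraph", "daily", "linear",  12,    5,
    "total_activity_count",      "actigraph", "daily",   "count",  2.2e5, 0.25,
    "avg_activity_count",        "actigraph", "daily",   "linear", 180,   30,
    "max_activity_count",        "actigraph", "daily",   "count",  4000,  0.30,
    "duration_min",              "actigraph", "daily",   "linear", 950,   60,
    "pct_invalid_sw",            "actigraph", "daily",   "linear",   5,    2,
    "time_awake_min",            "actigraph", "daily",   "linear", 880,   60,
    "pct_time_awake",            "actigraph", "daily",   "linear",  92,    4,
    "time_sleeping_min",         "actigraph", "daily",   "linear",  60,   25,
    "pct_time_sleeping",         "actigraph", "daily",   "linear",   8,    4,
    # Philips Actiwatch, nightly summaries
    "total_activity_count",      "actigraph", "nightly", "count",  1.5e4, 0.35,
    "avg_activity_count",        "actigraph", "nightly", "linear",  30,   10,
    "max_activity_count",        "actigraph", "nightly", "count",   900,  0.35,
    "duration_min",              "actigraph", "nightly", "linear", 480,   45,
    "pct_invalid_sw",            "actigraph", "nightly", "linear",   4,    2,
    "time_awake_min",            "actigraph", "nightly", "linear",  50,   18,
    "pct_time_awake",            "actigraph", "nightly", "linear",  10,    4,
    "n_wake_bouts",              "actigraph", "nightly", "count",   25,   0.30,
    "avg_wake_bout_min",         "actigraph", "nightly", "linear", 2.2,  0.7,
    "time_sleeping_min",         "actigraph", "nightly", "linear", 420,   45,
    "pct_time_sleeping",         "actigraph", "nightly", "linear",  88,    5,
    "sleep_onset_latency_min",   "actigraph", "nightly", "linear",  20,   10,
    "time_rest_after_wake_min",  "actigraph", "nightly", "linear",  15,    7,
    "time_valid_rest_min",       "actigraph", "nightly", "linear", 450,   45,
    "sleep_efficiency",          "actigraph", "nightly", "linear",  85,    5,
    "sleep_start_time",          "actigraph", "nightly", "circular_minutes", 1380, 45,
    "rest_start_time",           "actigraph", "nightly", "circular_minutes", 1350, 45,
    "sleep_fragmentation",       "actigraph", "nightly", "linear",  20,    8,
    # Garmin vivofit
    "garmin_sedentary_sec",      "garmin",    "daily",   "linear", 5e4,  6000,
    "garmin_walking_sec",        "garmin",    "daily",   "linear", 7000, 2000,
    "total_steps",               "garmin",    "daily",   "count",  6000, 0.30,
    "n_epochs",                  "garmin",    "daily",   "count",    96, 0.10,
    "steps_nighttime",           "garmin",    "nightly", "count",   300, 0.50,
    # Smartphone PRO surveys (items 0-4, summary = item sum)
    "bidaily_summary",           "survey",    "bidaily", "linear",  NA,   NA,
    "feel_down",                 "survey",    "bidaily", "ordinal", NA,   NA,
    "feel_confused",             "survey",    "bidaily", "ordinal", NA,   NA,
    "feel_stressed",             "survey",    "bidaily", "ordinal", NA,   NA,
    "see_hear_things",           "survey",    "bidaily", "ordinal", NA,   NA,
    "feel_suspicious",           "survey",    "bidaily", "ordinal", NA,   NA,
    "trouble_sleeping",          "survey",    "bidaily", "ordinal", NA,   NA,
    "weekly_summary",            "survey",    "weekly",  "linear",  NA,   NA,
    "feel_anxious",              "survey",    "weekly",  "ordinal", NA,   NA,
    "feel_unmotivated",          "survey",    "weekly",  "ordinal", NA,   NA,
    "trouble_getting_done",      "survey",    "weekly",  "ordinal", NA,   NA,
    "missed_medication",         "survey",    "weekly",  "ordinal", NA,   NA
  )
}

# Channel id used internally for the latent correlation structure: one
# latent channel per (metric, period) row of the registry.
channel_id <- function(metric, period) paste(metric, period, sep = ".")

survey_items <- function(period) {
  reg <- metric_registry()
  reg$metric[reg$source == "survey" & reg$period == period &
               reg$scale_type == "ordinal"]
}

#' Named feature sets for predictive modelling
#'
#' Feature sets group device/survey metrics into the blocks used when
#' predicting clinical scales: actigraphy sleep (nightly) summaries,
#' actigraphy activity (daily) summaries, Garmin activity summaries and the
#' bidaily/weekly survey channels, plus their unions.
#'
#' @param name One of `"actigraph_sleep"`, `"actigraph_activity"`,
#'   `"actigraph_both"`, `"garmin_activity"`, `"survey_bidaily"`,
#'   `"survey_weekly"`, `"survey_both"`, `"all"`.
#' @return A tibble with columns `metric`, `period` naming the channels in
#'   the set.
#' @export
feature_set <- function(name) {
  reg <- metric_registry()
  pick <- switch(name,
    actigraph_sleep    = reg$source == "actigraph" & reg$period == "nightly",
    actigraph_activity = reg$source == "actigraph" & reg$period == "daily",
    actigraph_both     = reg$source == "actigraph",
    garmin_activity    = reg$source == "garmin",
    survey_bidaily     = reg$source == "survey" & reg$period == "bidaily",
    survey_weekly      = reg$source == "survey" & reg$period == "weekly",
    survey_both        = reg$source == "survey",
    all                = rep(TRUE, nrow(reg)),
    abort(paste0("unknown feature set '", name, "'"))
  )
  out <- reg[pick, c("metric", "period")]
  if (nrow(out) == 0) abort("empty feature set")
  out
}
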