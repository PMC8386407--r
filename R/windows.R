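#' Build biweekly assessment windows
#'
#' One feature window per clinical visit: the half-open interval
#' `(assessment_date - width_days, assessment_date]`, so the night ending on
#' the assessment day is included and, at exactly biweekly spacing, windows
#' of consecutive visits do not overlap. Windows reaching before study start
#' are flagged truncated.
#'
#' @param visits Visits tibble (needs `patient_id`, `date`).
#' @param width_days Window width in days (study rule: the 2 weeks
#'   immediately before the assessment).
#' @param start_date Calendar date of study day 1, used only to flag
#'   truncated windows; `NULL` disables the flag.
#' @return Tibble with `patient_id`, `assessment_date`, `window_start`
#'   (exclusive), `window_end` (inclusive), `truncated`.
#' @export
build_windows <- function(visits, width_days = 14, start_date = NULL) {
  out <- visits %>%
    distinct(.data$patient_id, .data$date) %>%
    arrange(.data$patient_id, .data$date) %>%
    mutate(
      assessment_date = .data$date,
      window_start = .data$date - width_days,
      window_end = .data$date
    ) %>%
    select(-"date")
  out$truncated <- if (is.null(start_date)) {
    FALSE
  } else {
    out$window_start + 1 < as.Date(start_date)
  }
  out
}

scheduled_in_window <- function(period, window_start, window_end, start_date) {
  days <- seq(window_start + 1, window_end, by = "day")
  day_no <- as.integer(days - as.Date(start_date)) + 1
  switch(period,
    daily = ,
    nightly = length(days),
    bidaily = sum(day_no %% 2 == 0),
    weekly = sum(day_no %% 7 == 0),
    length(days)
  )
}

#' Aggregate one metric over one window
#'
#' Mean and SD of the samples falling in the half-open interval
#' `(interval[1], interval[2]]`. Linear metrics use the arithmetic mean and
#' sample SD (n-1 denominator); circular clock-time metrics use the
#' circular mean and circular SD in minutes. The SD is reported only when
#' at least two samples are present, and the feature is marked missing when
#' the fraction of scheduled days with data falls below `min_coverage`.
#'
#' @param dates,values Sample dates and values of one patient-metric
#'   stream.
#' @param interval Length-2 vector of dates, window `(start, end]`.
#' @param scale_type `"linear"`, `"count"`, `"ordinal"` or
#'   `"circular_minutes"`.
#' @param min_coverage Minimum coverage fraction for the feature to be
#'   considered observed.
#' @param scheduled Number of scheduled sample days in the interval
#'   (defaults to the interval length in days).
#' @return One-row tibble: `mean`, `sd`, `n`, `coverage`, `missing`.
#' @examples
#' aggregate_window(as.Date("2015-08-08") + 1:3, c(1, 2, 3),
#'                  as.Date(c("2015-08-08", "2015-08-22")))
#' @export
aggregate_window <- function(dates, values, interval, scale_type = "linear",
                             min_coverage = 0.5, scheduled = NULL) {
  if (!scale_type %in% c("linear", "count", "ordinal", "circular_minutes")) {
    abort(paste0("unknown scale_type '", scale_type, "'"))
  }
  interval <- as.Date(interval)
  scheduled <- scheduled %||% as.integer(interval[2] - interval[1])
  keep <- dates > interval[1] & dates <= interval[2] & !is.na(values)
  x <- values[keep]
  n <- length(x)
  cov <- if (scheduled > 0) n / scheduled else 0
  if (scale_type == "circular_minutes") {
    m <- if (n > 0) circular_mean_minutes(x) else NA_real_
    s <- if (n >= 2) circular_sd_minutes(x) else NA_real_
  } else {
    m <- if (n > 0) mean(x) else NA_real_
    s <- if (n >= 2) sd(x) else NA_real_
  }
  tibble(mean = m, sd = s, n = n, coverage = cov,
         missing = cov < min_coverage)
}

#' Window features for every visit and metric
#'
#' Computes, for each assessment window and each metric stream, the mean
#' and SD over the two weeks preceding the assessment (circular statistics
#' for clock-time metrics), with coverage bookkeeping against the metric's
#' sampling schedule.
#'
#' @param metrics Long metrics tibble.
#' @param windows Output of [build_windows()].
#' @param min_coverage Minimum coverage for a feature to be observed.
#' @param start_date Calendar date of study day 1 (sets survey schedules);
#'   defaults to the earliest metric date.
#' @return Tibble with one row per (patient, assessment date, metric,
#'   period): `mean`, `sd`, `n`, `coverage`, `missing`.
#' @export
window_features <- function(metrics, windows, min_coverage = 0.5,
                            start_date = min(metrics$date)) {
  joined <- dplyr::inner_join(
    metrics, windows,
    by = dplyr::join_by(patient_id, date > window_start, date <= window_end)
  )
  stats <- joined %>%
    group_by(.data$patient_id, .data$assessment_date, .data$window_start,
             .data$window_end, .data$metric, .data$period,
             .data$scale_type) %>%
    summarise(
      mean = if (.data$scale_type[1] == "circular_minutes") {
        circular_mean_minutes(.data$value)
      } else {
        mean(.data$value, na.rm = TRUE)
      },
      sd = if (dplyr::n() >= 2) {
        if (.data$scale_type[1] == "circular_minutes") {
          circular_sd_minutes(.data$value)
        } else {
          sd(.data$value, na.rm = TRUE)
        }
      } else {
        NA_real_
      },
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  # every (window, metric) pair, including ones with zero samples
  metric_kinds <- metrics %>% distinct(.data$metric, .data$period,
                                       .data$scale_type)
  full <- tidyr::expand_grid(
    windows %>% select("patient_id", "assessment_date", "window_start",
                       "window_end"),
    metric_kinds
  )
  out <- full %>%
    left_join(stats, by = names(full)) %>%
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)))
  out$scheduled <- mapply(
    scheduled_in_window, out$period, out$window_start, out$window_end,
    MoreArgs = list(start_date = start_date)
  )
  out %>%
    mutate(
      coverage = if_else(.data$scheduled > 0, .data$n / .data$scheduled, 0),
      missing = .data$coverage < min_coverage
    ) %>%
    select("patient_id", "assessment_date", "metric", "period",
           "scale_type", "mean", "sd", "n", "coverage", "missing")
}

#' Assemble a visit-aligned feature matrix
#'
#' Spreads the windowed summaries of one named [feature_set()] into a wide
#' matrix with one row per (patient, assessment date) and two columns per
#' metric (`*_mean`, `*_sd`). Features below the coverage threshold are
#' `NA` (imputation happens inside training folds during cross-validation,
#' never here); columns that are missing everywhere are dropped with a
#' message.
#'
#' @param features Output of [window_features()].
#' @param feature_set_name One of the names accepted by [feature_set()].
#' @return Wide tibble: `patient_id`, `assessment_date`, feature columns.
#' @export
assemble_feature_matrix <- function(features, feature_set_name) {
  set <- feature_set(feature_set_name)
  sel <- features %>%
    semi_join(set, by = c("metric", "period")) %>%
    mutate(
      mean = if_else(.data$missing, NA_real_, .data$mean),
      sd = if_else(.data$missing, NA_real_, .data$sd),
      key = paste(.data$metric, .data$period, sep = "_")
    )
  if (nrow(sel) == 0) abort("no features found for this feature set")
  wide <- sel %>%
    select("patient_id", "assessment_date", "key", "mean", "sd") %>%
    tidyr::pivot_wider(
      names_from = "key", values_from = c("mean", "sd"),
      names_glue = "{key}_{.value}"
    )
  feat_cols <- setdiff(names(wide), c("patient_id", "assessment_date"))
  all_na <- feat_cols[vapply(wide[feat_cols],
                             function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    inform(paste0("dropping all-missing feature column(s): ",
                  paste(all_na, collapse = ", ")))
    wide <- wide[, setdiff(names(wide), all_na)]
  }
  wide
}
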