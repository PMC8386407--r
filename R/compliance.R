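#' Data coverage and wear-time compliance
#'
#' Summarises how completely each of the four streams (Philips Actiwatch,
#' Garmin vivofit, bidaily PRO survey, weekly PRO survey) was used over an
#' observation window. A device-day is *covered* when any data exist and
#' *compliant* when the device was worn at least `wear_threshold` of 24
#' hours (with no wear-time table, a day with data counts as worn); a
#' scheduled survey slot is compliant iff a response exists. A patient-day
#' is compliant when all streams scheduled that day are compliant or at
#' least 2 of the 4 streams are.
#'
#' @param metrics Long metrics tibble.
#' @param window_start,window_end Half-open observation window
#'   `(window_start, window_end]` of calendar dates.
#' @param wear Optional tibble `(patient_id, source, date, wear_minutes)`
#'   of daily wear time for the device streams.
#' @param wear_threshold Fraction of 24 h required for a worn device-day
#'   (study rule: 0.5).
#' @param start_date Calendar date of study day 1 (sets the bidaily/weekly
#'   survey schedule); defaults to the earliest metric date.
#' @return A `psymon_compliance` list: `streams` (per-stream scheduled
#'   days, coverage and compliance fractions), `patient_days` (per
#'   patient-day stream counts and the compliant flag) and the window.
#' @export
compute_compliance <- function(metrics, window_start, window_end,
                               wear = NULL, wear_threshold = 0.5,
                               start_date = min(metrics$date)) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_end <= window_start) abort("observation window is empty")
  in_window <- metrics %>%
    filter(.data$date > window_start, .data$date <= window_end)
  empty <- nrow(in_window) == 0
  if (empty) {
    warn("observation window contains no data; compliance report is empty")
  }

  patients <- sort(unique(metrics$patient_id))
  days <- seq(window_start + 1, window_end, by = "day")
  day_no <- as.integer(days - start_date) + 1
  stream_sched <- list(
    actigraph = rep(TRUE, length(days)),
    garmin = rep(TRUE, length(days)),
    survey_bidaily = day_no %% 2 == 0,
    survey_weekly = day_no %% 7 == 0
  )

  grid <- tidyr::expand_grid(patient_id = patients, date = days)
  per_stream_day <- purrr::imap(stream_sched, function(sched, stream) {
    sched_days <- days[sched]
    g <- grid %>% filter(.data$date %in% sched_days)
    if (stream %in% c("actigraph", "garmin")) {
      present <- in_window %>%
        filter(.data$source == stream) %>%
        distinct(.data$patient_id, .data$date) %>%
        mutate(has_data = TRUE)
      g <- g %>% left_join(present, by = c("patient_id", "date")) %>%
        mutate(has_data = !is.na(.data$has_data))
      if (is.null(wear)) {
        g$compliant <- g$has_data
      } else {
        w <- wear %>% filter(.data$source == stream)
        g <- g %>%
          left_join(w[, c("patient_id", "date", "wear_minutes")],
                    by = c("patient_id", "date")) %>%
          mutate(compliant = .data$has_data &
                   !is.na(.data$wear_minutes) &
                   .data$wear_minutes >= wear_threshold * 1440) %>%
          select(-"wear_minutes")
      }
    } else {
      per <- sub("survey_", "", stream)
      present <- in_window %>%
        filter(.data$source == "survey", .data$period == per) %>%
        distinct(.data$patient_id, .data$date) %>%
        mutate(has_data = TRUE)
      g <- g %>% left_join(present, by = c("patient_id", "date")) %>%
        mutate(has_data = !is.na(.data$has_data),
               compliant = .data$has_data)
    }
    g$stream <- stream
    g
  })
  detail <- dplyr::bind_rows(per_stream_day)

  streams <- detail %>%
    group_by(stream = .data$stream) %>%
    summarise(
      scheduled_days = dplyr::n(),
      days_with_data = sum(.data$has_data),
      compliant_days = sum(.data$compliant),
      data_coverage = mean(.data$has_data),
      device_compliance = mean(.data$compliant),
      .groups = "drop"
    )

  patient_days <- detail %>%
    group_by(patient_id = .data$patient_id, date = .data$date) %>%
    summarise(
      n_streams_scheduled = dplyr::n(),
      n_streams_compliant = sum(.data$compliant),
      compliant = sum(.data$compliant) == dplyr::n() |
        sum(.data$compliant) >= 2,
      .groups = "drop"
    )

  structure(
    list(
      streams = streams,
      patient_days = patient_days,
      window = c(start = window_start, end = window_end),
      wear_threshold = wear_threshold
    ),
    class = "psymon_compliance"
  )
}
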