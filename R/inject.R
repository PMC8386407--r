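# Deterministic per-stage seed derivation: a master seed plus a stage label
# always map to the same 31-bit seed, so toggling one pipeline stage never
# perturbs another stage's randomness.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Inject a pre-relapse deviation into a simulated cohort
#'
#' Applies the behavioural signature of an approaching relapse to the
#' streams of the specified patients, leaving all pre-onset data untouched:
#'
#' * the nightly sleep start time drifts linearly on the clock circle by
#'   `sleep_onset_drift_min_per_week` from `onset_day` on;
#' * daily total steps are spread about the patient's pre-onset mean so
#'   their variance is multiplied by `activity_variance_multiplier`;
#' * the named survey items are spiked (+2 points, capped at 4) and the
#'   affected summary scores recomputed as item sums;
#' * at the first PANSS visit on or after `onset_day`, item P1 is raised to
#'   `panss_positive_item_target` (if not already there) and the PANSS
#'   total recomputed, so the study relapse criterion fires.
#'
#' @param metrics Long metrics tibble (as produced by [simulate_cohort()]).
#' @param visits Clinical visits tibble.
#' @param spec A [relapse_spec()].
#' @param start_date Calendar date of study day 1 (defaults to the earliest
#'   metric date).
#' @return A list with modified `metrics` and `visits`.
#' @export
inject_relapse <- function(metrics, visits, spec,
                           start_date = min(metrics$date)) {
  stopifnot(inherits(spec, "psymon_relapse_spec"))
  valid <- sort(unique(c(metrics$patient_id, visits$patient_id)))
  unknown <- setdiff(spec$patient_ids, valid)
  if (length(unknown)) {
    abort(paste0(
      "unknown patient id(s): ", paste(unknown, collapse = ", "),
      "; valid ids: ", paste(valid, collapse = ", ")
    ))
  }
  onset_date <- start_date + spec$onset_day - 1
  max_date <- max(metrics$date)
  if (onset_date > max_date) {
    abort("streams do not cover spec onset_day")
  }
  day_no <- as.numeric(metrics$date - start_date) + 1
  hit <- metrics$patient_id %in% spec$patient_ids & day_no >= spec$onset_day

  # sleep-onset drift (minutes per week, on the circle)
  if (spec$sleep_onset_drift_min_per_week != 0) {
    sel <- hit & metrics$metric == "sleep_start_time"
    offset <- spec$sleep_onset_drift_min_per_week *
      (day_no[sel] - spec$onset_day) / 7
    metrics$value[sel] <- round(metrics$value[sel] + offset) %% 1440
  }

  # step-count variance inflation about the pre-onset mean
  if (spec$activity_variance_multiplier != 1) {
    for (pid in spec$patient_ids) {
      pre <- metrics$patient_id == pid & metrics$metric == "total_steps" &
        day_no < spec$onset_day
      post <- hit & metrics$patient_id == pid & metrics$metric == "total_steps"
      if (!any(pre) || !any(post)) next
      m <- mean(metrics$value[pre])
      metrics$value[post] <- pmax(0, round(
        m + sqrt(spec$activity_variance_multiplier) * (metrics$value[post] - m)
      ))
    }
  }

  # survey symptom spikes, with summary scores kept consistent
  if (length(spec$survey_spike_items)) {
    sel <- hit & metrics$metric %in% spec$survey_spike_items
    metrics$value[sel] <- pmin(4, metrics$value[sel] + 2)
    touched <- unique(metrics[sel, c("patient_id", "period", "date")])
    for (r in seq_len(nrow(touched))) {
      key <- metrics$patient_id == touched$patient_id[r] &
        metrics$period == touched$period[r] & metrics$date == touched$date[r]
      items <- key & metrics$scale_type == "ordinal"
      summ <- key & metrics$metric %in% c("bidaily_summary", "weekly_summary")
      if (any(summ)) metrics$value[summ] <- sum(metrics$value[items])
    }
  }

  # PANSS positive item at the first post-onset assessment
  if (!is.null(spec$panss_positive_item_target)) {
    for (pid in spec$patient_ids) {
      idx <- which(visits$patient_id == pid & visits$date >= onset_date &
                     !is.na(visits$panss_total))
      if (!length(idx)) next
      first <- idx[which.min(visits$date[idx])]
      visits$panss_p1[first] <- max(visits$panss_p1[first],
                                    spec$panss_positive_item_target)
      visits$panss_total[first] <-
        sum(unlist(visits[first, panss_item_cols]))
    }
  }

  list(metrics = metrics, visits = visits)
}

#' Drop device-days and survey responses to emulate non-wear
#'
#' Each device-day (all metrics of one device for one patient on one date)
#' is dropped independently with probability `1 - wear_prob`; each scheduled
#' survey slot is dropped with probability `1 - response_prob`. Dropped
#' entries are absent from the output, never zero-filled.
#'
#' @param metrics Long metrics tibble.
#' @param wear_prob Per device-day wear probability in `[0, 1]`.
#' @param seed Integer seed (the drop pattern is reproducible).
#' @param response_prob Per survey-slot response probability (defaults to
#'   `wear_prob`).
#' @return The metrics tibble with gaps.
#' @export
apply_missingness <- function(metrics, wear_prob, seed,
                              response_prob = wear_prob) {
  if (wear_prob < 0 || wear_prob > 1) abort("wear_prob must be in [0, 1]")
  if (response_prob < 0 || response_prob > 1) {
    abort("response_prob must be in [0, 1]")
  }
  if (wear_prob == 1 && response_prob == 1) return(metrics)
  withr::with_seed(seed, {
    dev_keys <- metrics %>%
      filter(.data$source != "survey") %>%
      distinct(.data$patient_id, .data$source, .data$date) %>%
      arrange(.data$patient_id, .data$source, .data$date)
    dev_keys$keep <- runif(nrow(dev_keys)) < wear_prob

    srv_keys <- metrics %>%
      filter(.data$source == "survey") %>%
      distinct(.data$patient_id, .data$period, .data$date) %>%
      arrange(.data$patient_id, .data$period, .data$date)
    srv_keys$keep <- runif(nrow(srv_keys)) < response_prob

    dropped_dev <- dev_keys[!dev_keys$keep, c("patient_id", "source", "date")]
    dropped_srv <- srv_keys[!srv_keys$keep, c("patient_id", "period", "date")]
    metrics %>%
      anti_join(dropped_dev, by = c("patient_id", "source", "date")) %>%
      anti_join(
        dplyr::mutate(dropped_srv, source = "survey"),
        by = c("patient_id", "source", "period", "date")
      )
  })
}
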