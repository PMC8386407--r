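#' Configure a synthetic monitoring cohort
#'
#' Defines the generative conditions for [simulate_cohort()]: cohort size and
#' follow-up length, the clinical visit cadences, the variance decomposition
#' that sets the within-patient stability (ICC) of every channel, the target
#' cross-channel correlation structure, device wear and survey response
#' probabilities, and an optional pre-relapse injection.
#'
#' Every generated channel decomposes as a patient-level trait plus
#' day-level noise, both standard-normal on the latent scale:
#' \deqn{u_{ict} = (b_{ic} + e_{ict}) / \sqrt{\sigma_b^2 + \sigma_e^2},}
#' with \eqn{b_i \sim N(0, \sigma_b^2 R)} across channels and
#' \eqn{e_{it} \sim N(0, \sigma_e^2 R)} i.i.d. over days. The implied
#' intraclass correlation of every channel is
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)} and the correlation between
#' two channels is the corresponding entry of `cross_corr` (applied to both
#' components, so channels with a zero entry are exactly independent).
#'
#' @param n_patients Number of patients.
#' @param observation_days Follow-up length in days (study default 120, i.e.
#'   a 4-month observation period).
#' @param visit_schedule Named cadences in days for the clinical scales.
#'   Defaults: PANSS and BPRS every 14 days; CGI-S, CDS, YMRS, PSQI and YPAS
#'   every 28 days.
#' @param latent_trait_sd Between-patient SD \eqn{\sigma_b} on the latent
#'   scale (default `sqrt(0.6)`, i.e. generative ICC 0.6).
#' @param residual_sd Within-patient day-level SD \eqn{\sigma_e} (default
#'   `sqrt(0.4)`).
#' @param cross_corr Optional named symmetric correlation matrix over a
#'   subset of latent channel ids (see [latent_channels()]); unnamed
#'   channels are independent. Must be positive semidefinite with unit
#'   diagonal.
#' @param wear_prob Probability a device is worn on a given day, per
#'   device-day (default 0.94; non-wear drops all of that device's metrics
#'   for the day).
#' @param survey_response_prob Probability a scheduled survey slot is
#'   answered (default 0.85).
#' @param relapse Optional [relapse_spec()].
#' @param channels Optional character vector of device/survey metric names
#'   to generate (default: the full [metric_registry()] vocabulary).
#'   Clinical scales are always generated.
#' @param seed Integer seed; identical configs and seeds reproduce the
#'   cohort bit-for-bit.
#' @param start_date Calendar date of study day 1.
#' @return A validated `psymon_sim_config` list.
#' @seealso [simulate_cohort()], [relapse_spec()]
#' @export
sim_config <- function(n_patients,
                       observation_days = 120,
                       visit_schedule = c(
                         panss = 14, bprs = 14, cgi_s = 28, cds = 28,
                         ymrs = 28, psqi = 28, ypas = 28
                       ),
                       latent_trait_sd = sqrt(0.6),
                       residual_sd = sqrt(0.4),
                       cross_corr = NULL,
                       wear_prob = 0.94,
                       survey_response_prob = 0.85,
                       relapse = NULL,
                       channels = NULL,
                       seed = 1,
                       start_date = as.Date("2015-08-08")) {
  stopifnot(
    length(n_patients) == 1, n_patients >= 1,
    length(observation_days) == 1, observation_days >= 1,
    latent_trait_sd >= 0, residual_sd >= 0,
    latent_trait_sd + residual_sd > 0
  )
  if (wear_prob < 0 || wear_prob > 1) abort("wear_prob must be in [0, 1]")
  if (survey_response_prob < 0 || survey_response_prob > 1) {
    abort("survey_response_prob must be in [0, 1]")
  }
  required <- c("panss", "bprs", "cgi_s", "cds", "ymrs", "psqi", "ypas")
  missing_scales <- setdiff(required, names(visit_schedule))
  if (length(missing_scales)) {
    abort(paste0("visit_schedule lacks cadences for: ",
                 paste(missing_scales, collapse = ", ")))
  }
  if (observation_days < max(visit_schedule)) {
    abort("observation_days must cover the longest visit cadence")
  }
  if (!is.null(cross_corr)) validate_cross_corr(cross_corr)
  if (!is.null(relapse)) {
    if (!inherits(relapse, "psymon_relapse_spec")) {
      abort("relapse must be built with relapse_spec()")
    }
    if (relapse$onset_day < 1 || relapse$onset_day > observation_days) {
      abort("relapse onset_day must fall within the observation period")
    }
  }
  if (!is.null(channels)) {
    unknown <- setdiff(channels, metric_registry()$metric)
    if (length(unknown)) {
      abort(paste0("unknown metric(s) in channels: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      observation_days = as.integer(observation_days),
      visit_schedule = visit_schedule,
      latent_trait_sd = latent_trait_sd,
      residual_sd = residual_sd,
      cross_corr = cross_corr,
      wear_prob = wear_prob,
      survey_response_prob = survey_response_prob,
      relapse = relapse,
      channels = channels,
      seed = as.integer(seed),
      start_date = start_date
    ),
    class = "psymon_sim_config"
  )
}

validate_cross_corr <- function(cross_corr) {
  if (!is.matrix(cross_corr) || nrow(cross_corr) != ncol(cross_corr)) {
    abort("cross_corr must be a square matrix")
  }
  if (is.null(rownames(cross_corr)) ||
      !identical(rownames(cross_corr), colnames(cross_corr))) {
    abort("cross_corr must have matching channel row/column names")
  }
  if (any(abs(cross_corr) > 1 + 1e-12)) {
    abort("cross_corr entries must lie in [-1, 1]")
  }
  if (any(abs(diag(cross_corr) - 1) > 1e-12)) {
    abort("cross_corr must have a unit diagonal")
  }
  if (max(abs(cross_corr - t(cross_corr))) > 1e-12) {
    abort("cross_corr must be symmetric")
  }
  ev <- eigen(cross_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(
      "cross_corr is not positive semidefinite (smallest eigenvalue %.6g)",
      min(ev)
    ))
  }
  invisible(cross_corr)
}

#' Specify an injectable pre-relapse deviation
#'
#' Describes the behavioural signature injected into a synthetic cohort to
#' emulate the run-up to a relapse: a linear drift in sleep onset time
#' (earlier sleep as relapse approaches), inflated day-to-day step-count
#' variability, spikes in self-reported symptom items, and a PANSS positive
#' item raised to the relapse threshold at the first post-onset visit.
#'
#' @param patient_ids Patients receiving the injection.
#' @param onset_day Study day (1-based) the deviation starts.
#' @param sleep_onset_drift_min_per_week Signed drift of the sleep start
#'   time in minutes per week from `onset_day` on (negative = earlier;
#'   default -15, i.e. about 90 minutes earlier after 6 weeks).
#' @param activity_variance_multiplier Factor (> 0) applied to the variance
#'   of daily total steps about the patient's pre-onset mean.
#' @param survey_spike_items Survey item names spiked (+2 points, capped at
#'   4) from `onset_day` on; summary scores are recomputed.
#' @param panss_positive_item_target Score (5-7) forced onto PANSS item P1
#'   at the first post-onset PANSS visit so the study relapse criterion
#'   fires, or `NULL` to leave the clinical scales untouched.
#' @return A `psymon_relapse_spec` list.
#' @export
relapse_spec <- function(patient_ids,
                         onset_day,
                         sleep_onset_drift_min_per_week = -15,
                         activity_variance_multiplier = 1,
                         survey_spike_items = character(),
                         panss_positive_item_target = 5) {
  stopifnot(length(onset_day) == 1, onset_day >= 1)
  if (activity_variance_multiplier <= 0) {
    abort("activity_variance_multiplier must be > 0")
  }
  if (!is.null(panss_positive_item_target)) {
    if (panss_positive_item_target < 1 || panss_positive_item_target > 7) {
      abort("panss_positive_item_target must be in 1..7")
    }
  }
  known_items <- metric_registry()$metric[metric_registry()$scale_type == "ordinal"]
  bad <- setdiff(survey_spike_items, known_items)
  if (length(bad)) {
    abort(paste0("unknown survey item(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      patient_ids = patient_ids,
      onset_day = as.integer(onset_day),
      sleep_onset_drift_min_per_week = sleep_onset_drift_min_per_week,
      activity_variance_multiplier = activity_variance_multiplier,
      survey_spike_items = survey_spike_items,
      panss_positive_item_target = panss_positive_item_target
    ),
    class = "psymon_relapse_spec"
  )
}
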