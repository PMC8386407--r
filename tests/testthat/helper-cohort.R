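# Shared fixtures, generated in code and cached per test run.

the <- new.env(parent = emptyenv())

# a small full-vocabulary cohort reused by IO / window / pipeline tests
small_cohort <- function() {
  if (is.null(the$small_cohort)) {
    the$small_cohort <- simulate_cohort(
      sim_config(n_patients = 3, observation_days = 60, seed = 101)
    )
  }
  the$small_cohort
}

study_start <- as.Date("2015-08-08")

# a visit row with every PANSS item at `fill`, overridable per subscale
make_visit <- function(p = rep(1, 7), n = rep(1, 7), g = rep(1, 16),
                       med_change = FALSE, date = study_start + 14) {
  v <- tibble::tibble(patient_id = "P001", date = date,
                      med_change = med_change)
  v[paste0("panss_p", 1:7)] <- as.list(as.numeric(p))
  v[paste0("panss_n", 1:7)] <- as.list(as.numeric(n))
  v[paste0("panss_g", 1:16)] <- as.list(as.numeric(g))
  v$panss_total <- sum(p) + sum(n) + sum(g)
  v
}

# long-format stream for a single patient-metric
make_stream <- function(values, metric = "time_sleeping_min",
                        period = "nightly", scale_type = "linear",
                        source = "actigraph", patient_id = "P001",
                        start = study_start) {
  tibble::tibble(
    patient_id = patient_id, metric = metric, source = source,
    period = period, scale_type = scale_type,
    date = start + seq_along(values) - 1,
    value = values
  )
}
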