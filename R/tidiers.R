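#' Tidy the per-repeat results of a cross-validation run
#'
#' @param x A `psymon_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per completed repeat (`repeat_id`, `rmse`,
#'   `r2`, `n_pred`).
#' @exportS3Method generics::tidy
tidy.psymon_cv <- function(x, ...) x$by_repeat

#' One-row performance summary of a cross-validation run
#'
#' @param x A `psymon_cv` object.
#' @param ... Unused.
#' @return One-row tibble: `outcome`, `rmse_mean`, `rmse_sd`, `r2_mean`,
#'   `r2_sd` (SDs across repeats), `n_repeats`, `n_skipped`.
#' @exportS3Method generics::glance
glance.psymon_cv <- function(x, ...) {
  x$summary %>% mutate(n_skipped = x$n_skipped)
}

#' Tidy the coefficients of a fitted elastic net
#'
#' @param x A `psymon_enet` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` at the selected `(alpha,
#'   lambda)`.
#' @exportS3Method generics::tidy
tidy.psymon_enet <- function(x, ...) {
  b <- as.matrix(stats::coef(x$fit, s = x$lambda))
  tibble(term = rownames(b), estimate = as.vector(b))
}

#' Tidy the alert stream of a patient monitor
#'
#' @param x A `psymon_monitor` object.
#' @param ... Unused.
#' @return The alerts tibble.
#' @exportS3Method generics::tidy
tidy.psymon_monitor <- function(x, ...) x$alerts

#' Summary counts of a patient monitor
#'
#' @param x A `psymon_monitor` object.
#' @param ... Unused.
#' @return One-row tibble with patient id, monitored/skipped metric counts
#'   and alert counts by kind.
#' @exportS3Method generics::glance
glance.psymon_monitor <- function(x, ...) {
  kinds <- c("point_outlier", "mean_shift", "variance_shift", "slope_change")
  counts <- vapply(kinds, function(k) sum(x$alerts$kind == k), integer(1))
  dplyr::bind_cols(
    tibble(patient_id = x$patient_id,
           n_metrics = length(x$series),
           n_skipped = nrow(x$skipped)),
    as_tibble(as.list(counts))
  )
}

#' Tidy a compliance report
#'
#' @param x A `psymon_compliance` object.
#' @param ... Unused.
#' @return The per-stream coverage/compliance tibble.
#' @exportS3Method generics::tidy
tidy.psymon_compliance <- function(x, ...) x$streams
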