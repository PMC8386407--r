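#' Flag relapse from PANSS items
#'
#' Applies the study relapse criterion to each clinical visit: a patient is
#' flagged as relapsing if any PANSS positive-subscale item (P1-P7) is rated
#' moderately severe or worse (score >= 5), if at least two
#' negative-subscale items (N1-N7) are >= 5, or if an increased PANSS total
#' required a change in antipsychotic medication (`total_increased` and
#' `med_change` both true).
#'
#' The PANSS total increase is supplied by the caller rather than
#' recomputed from a baseline, since no universal increase threshold
#' exists; missing item scores are an error, never silently imputed.
#'
#' @param visits Visits tibble with the 30 `panss_*` item columns and a
#'   logical `med_change` column.
#' @param total_increased Logical, recycled across rows or given per row:
#'   did the PANSS total increase relative to the reference assessment?
#' @return The input with a logical `relapse_flag` column appended.
#' @examples
#' v <- tibble::tibble(
#'   patient_id = "P001", date = as.Date("2015-09-01"), med_change = FALSE
#' )
#' v[paste0("panss_p", 1:7)] <- list(5, 1, 1, 1, 1, 1, 1)
#' v[paste0("panss_n", 1:7)] <- 1
#' v[paste0("panss_g", 1:16)] <- 1
#' flag_relapse(v)$relapse_flag # one positive item at 5 suffices
#' @export
flag_relapse <- function(visits, total_increased = FALSE) {
  pos_cols <- paste0("panss_p", 1:7)
  neg_cols <- paste0("panss_n", 1:7)
  need <- c(pos_cols, neg_cols)
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols)) {
    abort(paste0("visits lack PANSS item column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pos <- as.matrix(visits[, pos_cols])
  neg <- as.matrix(visits[, neg_cols])
  if (anyNA(pos) || anyNA(neg)) {
    abort("PANSS item scores contain missing values; cannot flag relapse")
  }
  if (min(pos, neg) < 1 || max(pos, neg) > 7) {
    abort("PANSS items must lie in 1..7")
  }
  med <- if ("med_change" %in% names(visits)) visits$med_change else FALSE
  n <- nrow(visits)
  total_increased <- rep_len(as.logical(total_increased), n)
  med <- rep_len(as.logical(med), n)
  visits$relapse_flag <-
    apply(pos >= 5, 1, any) |
    (rowSums(neg >= 5) >= 2) |
    (total_increased & med)
  visits
}
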