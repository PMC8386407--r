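#' Read and write long-format metric streams
#'
#' Metric streams are exchanged as CSV with columns
#' `patient_id,metric,period,date,value`: ISO-8601 dates, clock-time metrics
#' as `"HH:MM"`, everything else numeric. On read, each row is matched
#' against the [metric_registry()] vocabulary to recover its source and
#' scale type; unknown metric/period combinations are rejected unless
#' `allow_unknown = TRUE` (they are then treated as linear). Duplicate
#' `(patient, metric, period, date)` rows and malformed clock times are
#' rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @param allow_unknown Accept metrics outside the registry vocabulary.
#' @return `read_metrics()` a metrics tibble (`patient_id`, `metric`,
#'   `source`, `period`, `scale_type`, `date`, `value`); `write_metrics()`
#'   the path, invisibly. Writing then reading reproduces the tibble.
#' @export
read_metrics <- function(path, allow_unknown = FALSE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      metric = readr::col_character(),
      period = readr::col_character(),
      date = readr::col_date(),
      value = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("patient_id", "metric", "period", "date", "value")
  if (!all(need %in% names(raw))) {
    abort(paste0("metrics CSV must have columns: ", paste(need, collapse = ",")))
  }
  reg <- metric_registry()
  m <- match(paste(raw$metric, raw$period), paste(reg$metric, reg$period))
  if (anyNA(m) && !allow_unknown) {
    bad <- unique(paste0(raw$metric, " (", raw$period, ")")[is.na(m)])
    abort(paste0(
      "unknown metric/period combination(s): ",
      paste(head(bad, 5), collapse = ", "),
      "; pass allow_unknown = TRUE to keep them"
    ))
  }
  out <- raw %>%
    mutate(
      source = if_else(is.na(m), "unknown", reg$source[m]),
      scale_type = if_else(is.na(m), "linear", reg$scale_type[m])
    )

  dup <- which(duplicated(out[, c("patient_id", "metric", "period", "date")]) |
                 duplicated(out[, c("patient_id", "metric", "period", "date")],
                            fromLast = TRUE))
  if (length(dup)) {
    first <- out[dup[1], ]
    abort(sprintf(
      "duplicate rows for (%s, %s, %s, %s) at CSV lines %s",
      first$patient_id, first$metric, first$period, format(first$date),
      paste(dup[seq_len(min(10, length(dup)))] + 1, collapse = ", ")
    ))
  }

  circ <- out$scale_type == "circular_minutes"
  value <- rep(NA_real_, nrow(out))
  if (any(circ)) {
    parsed <- tryCatch(parse_hhmm(out$value[circ]), error = function(e) e)
    if (inherits(parsed, "error")) {
      bad_rows <- which(circ)[!grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$",
                                     out$value[circ])]
      abort(sprintf(
        "malformed clock time(s) at CSV line(s) %s: %s",
        paste(head(bad_rows + 1, 5), collapse = ", "),
        conditionMessage(parsed)
      ))
    }
    value[circ] <- parsed
  }
  num <- suppressWarnings(as.numeric(out$value[!circ]))
  if (anyNA(num) && !anyNA(out$value[!circ])) {
    bad_rows <- which(!circ)[is.na(num) & !is.na(out$value[!circ])]
    abort(sprintf("non-numeric value(s) at CSV line(s) %s",
                  paste(head(bad_rows + 1, 5), collapse = ", ")))
  }
  value[!circ] <- num
  counts <- out$scale_type == "count" & !is.na(value)
  if (any(value[counts] < 0 | value[counts] != round(value[counts]))) {
    abort("count metrics must be non-negative integers")
  }
  out$value <- value
  out %>%
    select("patient_id", "metric", "source", "period", "scale_type",
           "date", "value") %>%
    arrange(.data$patient_id, .data$source, .data$period, .data$metric,
            .data$date)
}

#' @rdname read_metrics
#' @param metrics Metrics tibble to serialize.
#' @export
write_metrics <- function(metrics, path) {
  out <- metrics %>%
    mutate(value = if_else(
      .data$scale_type == "circular_minutes",
      format_hhmm(.data$value),
      sprintf("%.17g", .data$value)
    )) %>%
    select("patient_id", "metric", "period", "date", "value")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write clinical visit tables
#'
#' Visits are exchanged as wide CSV: one row per patient-visit, columns for
#' the PANSS items and total, the other scale totals, PSQI components, YPAS
#' indices, visit-level survey summaries and the medication-change flag.
#' Item/total consistency (PANSS total = item sum, PSQI global = component
#' sum) and item ranges are checked on read.
#'
#' @param path CSV file path.
#' @return `read_visits()` a visits tibble; `write_visits()` the path,
#'   invisibly.
#' @export
read_visits <- function(path) {
  v <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_date(),
    med_change = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_visits(v)
  v
}

#' @rdname read_visits
#' @param visits Visits tibble to serialize.
#' @export
write_visits <- function(visits, path) {
  readr::write_csv(visits, path, progress = FALSE)
  invisible(path)
}

validate_visits <- function(visits) {
  if (!all(c("patient_id", "date") %in% names(visits))) {
    abort("visits need patient_id and date columns")
  }
  items <- intersect(panss_item_cols, names(visits))
  if (length(items) == 30 && "panss_total" %in% names(visits)) {
    it <- as.matrix(visits[, items])
    ok <- is.na(visits$panss_total) | !complete.cases(it) |
      abs(visits$panss_total - rowSums(it)) < 1e-8
    if (!all(ok)) {
      abort(sprintf("PANSS total differs from item sum at row(s) %s",
                    paste(head(which(!ok), 5), collapse = ", ")))
    }
    rng <- it[!is.na(it)]
    if (length(rng) && (min(rng) < 1 || max(rng) > 7)) {
      abort("PANSS items must lie in 1..7")
    }
  }
  comps <- intersect(paste0("psqi_c", 1:7), names(visits))
  if (length(comps) == 7 && "psqi_global" %in% names(visits)) {
    cm <- as.matrix(visits[, comps])
    ok <- is.na(visits$psqi_global) | !complete.cases(cm) |
      abs(visits$psqi_global - rowSums(cm)) < 1e-8
    if (!all(ok)) {
      abort(sprintf("PSQI global differs from component sum at row(s) %s",
                    paste(head(which(!ok), 5), collapse = ", ")))
    }
    rng <- cm[!is.na(cm)]
    if (length(rng) && (min(rng) < 0 || max(rng) > 3)) {
      abort("PSQI components must lie in 0..3")
    }
  }
  if ("cgi_s" %in% names(visits)) {
    cg <- visits$cgi_s[!is.na(visits$cgi_s)]
    if (length(cg) && (min(cg) < 1 || max(cg) > 7)) {
      abort("CGI-S must lie in 1..7")
    }
  }
  invisible(visits)
}

#' Write a simulated cohort to disk
#'
#' Serializes a [simulate_cohort()] result as three files in `dir`:
#' `metrics.csv` (long format), `visits.csv` (wide format) and `truth.json`
#' (generative parameters).
#'
#' @param cohort A `psymon_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_metrics(cohort$metrics, file.path(dir, "metrics.csv"))
  write_visits(cohort$visits, file.path(dir, "visits.csv"))
  truth <- cohort$truth
  truth$start_date <- format(truth$start_date)
  if (!is.null(truth$cross_corr)) {
    truth$cross_corr <- list(
      channels = rownames(cohort$truth$cross_corr),
      matrix = unname(apply(cohort$truth$cross_corr, 1, as.numeric,
                            simplify = FALSE))
    )
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
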