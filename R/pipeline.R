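#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: cohort input (simulated from a
#' [sim_config()] or read from metric/visit CSV files) -> compliance ->
#' window features -> pairwise associations and ICC -> elastic-net
#' prediction -> per-patient streaming monitor. Stages can be toggled;
#' every stage draws its randomness from a seed derived from the master
#' seed and the stage name, so disabling one stage never changes another's
#' results. When `output_dir` is given, each stage's tables are written as
#' CSV/JSON and listed in a manifest with MD5 checksums.
#'
#' @param config A [sim_config()] to simulate from, or a list
#'   `list(metrics = <path>, visits = <path>)` of CSV files.
#' @param stages Character subset of `c("compliance", "features",
#'   "associations", "icc", "prediction", "monitor")`.
#' @param outcomes Clinical scale columns modelled in the prediction stage.
#' @param feature_sets Feature sets (see [feature_set()]) used in the
#'   prediction stage.
#' @param association_pairs Tibble (`response`, `predictor`) for the
#'   association stage; defaults to all pairs of the five symptom scales.
#' @param icc_scales Scale columns whose ICC is reported.
#' @param cv_args List of extra arguments to [cross_validate()] (e.g.
#'   smaller `k`/`repeats` for quick runs).
#' @param monitor_cfg A [monitor_config()].
#' @param seed Master seed.
#' @param output_dir Optional directory for the serialized bundle.
#' @return A `psymon_bundle` list with one element per executed stage plus
#'   `manifest` when written to disk.
#' @export
run_pipeline <- function(config,
                         stages = c("compliance", "features", "associations",
                                    "icc", "prediction", "monitor"),
                         outcomes = c("panss_total", "bprs_total"),
                         feature_sets = c("actigraph_sleep", "survey_both"),
                         association_pairs = NULL,
                         icc_scales = c("panss_total", "bprs_total",
                                        "cds_total", "ymrs_total"),
                         cv_args = list(k = 5, repeats = 5),
                         monitor_cfg = monitor_config(),
                         seed = 1,
                         output_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(config, "psymon_sim_config")) {
    cohort <- simulate_cohort(config)
    start_date <- config$start_date
  } else if (is.list(config) && all(c("metrics", "visits") %in% names(config))) {
    cohort <- list(
      metrics = read_metrics(config$metrics),
      visits = read_visits(config$visits),
      truth = NULL
    )
    start_date <- min(cohort$metrics$date)
  } else {
    abort("config must be a sim_config() or list(metrics=, visits=) of paths")
  }

  bundle <- list(cohort = cohort, seed = seed, stages = stages)
  metrics <- cohort$metrics
  visits <- cohort$visits

  if ("compliance" %in% stages) {
    bundle$compliance <- compute_compliance(
      metrics,
      window_start = start_date - 1,
      window_end = max(metrics$date),
      start_date = start_date
    )
  }
  features <- NULL
  if (any(c("features", "associations", "prediction") %in% stages)) {
    windows <- build_windows(visits, start_date = start_date)
    features <- window_features(metrics, windows, start_date = start_date)
    bundle$windows <- windows
    bundle$features <- features
  }
  if ("associations" %in% stages) {
    pairs <- association_pairs %||% default_association_pairs()
    assoc_data <- visits
    bundle$associations <- association_matrix(assoc_data, pairs)
  }
  if ("icc" %in% stages) {
    bundle$icc <- purrr::map(icc_scales, function(s) {
      icc(visits[!is.na(visits[[s]]), ], s)
    }) %>% dplyr::bind_rows()
  }
  if ("prediction" %in% stages) {
    bundle$prediction <- purrr::map(outcomes, function(oc) {
      purrr::map(feature_sets, function(fs) {
        fm <- assemble_feature_matrix(features, fs)
        d <- visits %>%
          select("patient_id", "date", all_of(oc)) %>%
          dplyr::inner_join(fm, by = c("patient_id",
                                       date = "assessment_date"))
        cv <- rlang::exec(
          cross_validate, d, outcome = oc,
          seed = derive_seed(seed, paste0("cv-", oc, "-", fs)),
          !!!cv_args
        )
        cv$summary %>% mutate(feature_set = fs, .before = 1)
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
  }
  if ("monitor" %in% stages) {
    bundle$monitor <- metrics %>%
      dplyr::group_split(.data$patient_id) %>%
      purrr::map(monitor_patient, config = monitor_cfg,
                 start_date = start_date)
    names(bundle$monitor) <-
      purrr::map_chr(bundle$monitor, "patient_id")
    bundle$alerts <- purrr::map(bundle$monitor, "alerts") %>%
      dplyr::bind_rows()
  }
  if ("associations" %in% stages || "icc" %in% stages) {
    bundle$relapse_flags <- tryCatch(
      flag_relapse(visits[!is.na(visits$panss_total), ]) %>%
        select("patient_id", "date", "relapse_flag"),
      error = function(e) NULL
    )
  }

  if (!is.null(output_dir)) {
    bundle$manifest <- write_bundle(bundle, output_dir, start_date)
  }
  structure(bundle, class = "psymon_bundle")
}

default_association_pairs <- function() {
  scales <- c("panss_total", "bprs_total", "cgi_s", "cds_total", "ymrs_total")
  cmb <- utils::combn(scales, 2)
  tibble(response = cmb[1, ], predictor = cmb[2, ])
}

write_bundle <- function(bundle, dir, start_date) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    paths[[name]] <<- p
  }
  write_metrics(bundle$cohort$metrics, file.path(dir, "metrics.csv"))
  paths[["metrics.csv"]] <- file.path(dir, "metrics.csv")
  put_csv(bundle$cohort$visits, "visits.csv")
  if (!is.null(bundle$compliance)) put_csv(bundle$compliance$streams,
                                           "compliance.csv")
  if (!is.null(bundle$features)) put_csv(bundle$features, "features.csv")
  if (!is.null(bundle$associations)) put_csv(bundle$associations,
                                             "associations.csv")
  if (!is.null(bundle$icc)) put_csv(bundle$icc, "icc.csv")
  if (!is.null(bundle$prediction)) put_csv(bundle$prediction,
                                           "prediction.csv")
  if (!is.null(bundle$alerts)) put_csv(bundle$alerts, "alerts.csv")
  if (!is.null(bundle$relapse_flags)) put_csv(bundle$relapse_flags,
                                              "relapse_flags.csv")
  manifest <- tibble(
    file = names(paths),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  manifest
}

#' Render a plain-text report of a pipeline bundle
#'
#' Assembles a human-readable summary of every stage present in the
#' bundle: cohort size, stream coverage/compliance percentages, the
#' association table with "nc" entries for non-converged pairs, the ICC
#' table, prediction performance per outcome and feature set, relapse
#' flags and the alert timeline. Every number is taken from the bundle;
#' nothing is recomputed at render time, so regeneration is idempotent.
#' Missing stages render as absent sections.
#'
#' @param bundle A `psymon_bundle`.
#' @return A character vector of report lines, invisibly printable via
#'   `cat(render_report(b), sep = "\n")`.
#' @export
render_report <- function(bundle) {
  fmt_num <- function(x, digits = 2) {
    ifelse(is.na(x), "nc", formatC(x, digits = digits, format = "f"))
  }
  out <- c("# Wearable monitoring pipeline report", "")
  n_pat <- length(unique(bundle$cohort$visits$patient_id))
  out <- c(out, sprintf("Cohort: %d patients, %d metric rows, %d visits.",
                        n_pat, nrow(bundle$cohort$metrics),
                        nrow(bundle$cohort$visits)), "")
  if (!is.null(bundle$compliance)) {
    out <- c(out, "## Data coverage and compliance")
    s <- bundle$compliance$streams
    out <- c(out, sprintf(
      "- %s: coverage %.0f%%, compliance %.0f%%",
      s$stream, 100 * s$data_coverage, 100 * s$device_compliance
    ), "")
  } else {
    out <- c(out, "## Data coverage and compliance", "(absent)", "")
  }
  out <- c(out, "## Associations among clinical scales")
  if (!is.null(bundle$associations) && nrow(bundle$associations)) {
    a <- bundle$associations
    out <- c(out, sprintf(
      "- %s ~ %s: coefficient %s, p %s%s",
      a$response, a$predictor,
      ifelse(a$converged, fmt_num(a$coefficient), "nc"),
      ifelse(a$converged, fmt_num(a$p_value, 4), "nc"),
      ifelse(a$significant & !is.na(a$significant), " *", "")
    ), "")
  } else {
    out <- c(out, "(absent)", "")
  }
  out <- c(out, "## Within-patient stability (ICC)")
  if (!is.null(bundle$icc)) {
    out <- c(out, sprintf("- %s: ICC %s (var between %s, within %s)",
                          bundle$icc$scale, fmt_num(bundle$icc$icc),
                          fmt_num(bundle$icc$var_between),
                          fmt_num(bundle$icc$var_within)), "")
  } else {
    out <- c(out, "(absent)", "")
  }
  out <- c(out, "## Prediction performance")
  if (!is.null(bundle$prediction)) {
    p <- bundle$prediction
    out <- c(out, sprintf(
      "- %s | %s: RMSE %s (SD %s), R^2 %s (SD %s)",
      p$outcome, p$feature_set, fmt_num(p$rmse_mean), fmt_num(p$rmse_sd),
      fmt_num(p$r2_mean), fmt_num(p$r2_sd)
    ), "")
  } else {
    out <- c(out, "(absent)", "")
  }
  out <- c(out, "## Relapse flags")
  if (!is.null(bundle$relapse_flags)) {
    fl <- bundle$relapse_flags[bundle$relapse_flags$relapse_flag, ]
    if (nrow(fl)) {
      out <- c(out, sprintf("- %s on %s", fl$patient_id, format(fl$date)), "")
    } else {
      out <- c(out, "(none)", "")
    }
  } else {
    out <- c(out, "(absent)", "")
  }
  out <- c(out, "## Streaming alerts")
  if (!is.null(bundle$alerts)) {
    if (nrow(bundle$alerts)) {
      tab <- count(bundle$alerts, .data$kind)
      out <- c(out, sprintf("- %s: %d", tab$kind, tab$n), "")
    } else {
      out <- c(out, "(none)", "")
    }
  } else {
    out <- c(out, "(absent)", "")
  }
  out
}
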