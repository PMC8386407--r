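ordinal_cuts <- c(0.25, 0.9, 1.5, 2.05)          # survey items 0-4
panss_item_cuts <- c(1.0, 1.8, 2.4, 2.9, 3.3, 3.7) # items 1-7, mostly 1-2
psqi_component_cuts <- c(0.2, 1.1, 2.0)            # components 0-3
panss_item_loading <- 0.7                          # item ~ scale latent

panss_item_cols <- c(
  paste0("panss_p", 1:7), paste0("panss_n", 1:7), paste0("panss_g", 1:16)
)

#' Latent channel identifiers of the cohort generator
#'
#' Every generated stream (device metric per period, survey item, clinical
#' scale) corresponds to one latent Gaussian channel; `cross_corr` in
#' [sim_config()] is named by these identifiers. Device and survey channels
#' are `"<metric>.<period>"`; clinical channels are the scale names.
#'
#' @param config Optional `psymon_sim_config`; when given, the device
#'   channel list honours its `channels` restriction.
#' @return Character vector of channel ids.
#' @export
latent_channels <- function(config = NULL) {
  reg <- metric_registry()
  reg <- reg[!reg$metric %in% c("bidaily_summary", "weekly_summary"), ]
  if (!is.null(config) && !is.null(config$channels)) {
    reg <- reg[reg$metric %in% config$channels, ]
  }
  c(
    channel_id(reg$metric, reg$period),
    "panss", "bprs_total", "cgi_s", "cds_total", "ymrs_total",
    paste0("psqi_c", 1:7),
    "ypas_global", "ypas_vigorous", "ypas_leisure_walking",
    "ypas_moving", "ypas_standing", "ypas_sitting"
  )
}

# Square-root factor of the full channel correlation matrix (identity
# outside the named cross_corr block). Eigen-based so PSD (rank-deficient)
# targets are accepted.
correlation_factor <- function(ids, cross_corr) {
  C <- length(ids)
  R <- diag(C)
  if (!is.null(cross_corr)) {
    idx <- match(rownames(cross_corr), ids)
    if (anyNA(idx)) {
      abort(paste0(
        "cross_corr names not among latent channels: ",
        paste(rownames(cross_corr)[is.na(idx)], collapse = ", ")
      ))
    }
    R[idx, idx] <- cross_corr
  }
  eig <- eigen(R, symmetric = TRUE)
  eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), C)
}

schedule_days <- function(period, n_days) {
  switch(period,
    daily = seq_len(n_days),
    nightly = seq_len(n_days),
    bidaily = seq(2, n_days, by = 2),
    weekly = seq(7, n_days, by = 7),
    abort(paste0("unknown period '", period, "'"))
  )
}

#' Simulate a synthetic wearable-monitoring cohort
#'
#' Generates the three tables the analysis pipeline consumes: a long-format
#' stream of device and survey metrics, a wide table of clinical visits, and
#' a truth record holding the generative parameters. All channels share the
#' latent trait-plus-noise structure described in [sim_config()], then map
#' to their natural scales: linear channels are affine transforms, clock
#' times live on the 1440-minute circle, counts are exponentiated Gaussians
#' rounded and floored at zero, and survey items are 0-4 ordinals obtained
#' by binning the latent value at fixed cut points (summary scores are item
#' sums). PANSS/PSQI totals are always the sum of their generated items.
#'
#' When the config carries a [relapse_spec()], the pre-relapse deviation is
#' injected with [inject_relapse()]; device non-wear and missed surveys are
#' applied with [apply_missingness()]. A fixed config and seed reproduces
#' the cohort exactly.
#'
#' @param config A [sim_config()].
#' @return A `psymon_cohort` list with elements `metrics` (tibble:
#'   `patient_id`, `metric`, `source`, `period`, `scale_type`, `date`,
#'   `value`), `visits` (one row per patient-visit, `NA` for scales not
#'   scheduled that day) and `truth` (generative ICC, correlation target,
#'   relapse metadata, seed).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 3, seed = 42))
#' dplyr::count(cohort$metrics, source)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "psymon_sim_config"))
  reg <- metric_registry()
  if (!is.null(config$channels)) {
    reg <- reg[reg$metric %in% config$channels, ]
  }
  ids <- latent_channels(config)
  A <- correlation_factor(ids, config$cross_corr)
  sb <- config$latent_trait_sd
  se <- config$residual_sd
  s_tot <- sqrt(sb^2 + se^2)
  n_days <- config$observation_days
  dates <- config$start_date + seq_len(n_days) - 1
  C <- length(ids)

  item_rows <- reg[reg$scale_type == "ordinal", ]
  summary_rows <- reg[reg$metric %in% c("bidaily_summary", "weekly_summary"), ]
  device_rows <- reg[reg$source != "survey", ]

  out <- withr::with_seed(config$seed, {
    metrics_by_patient <- vector("list", config$n_patients)
    visits_by_patient <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", i)
      b <- sb * as.vector(A %*% rnorm(C))
      E <- se * (A %*% matrix(rnorm(C * n_days), C, n_days))
      U <- (b + E) / s_tot # C x n_days, standard normal latent values
      rownames(U) <- ids

      # device streams: one long block per patient, built columnwise
      sched_list <- lapply(device_rows$period, schedule_days, n_days = n_days)
      dev_values <- vector("list", nrow(device_rows))
      for (r in seq_len(nrow(device_rows))) {
        d <- sched_list[[r]]
        u <- U[channel_id(device_rows$metric[r], device_rows$period[r]), d]
        mu <- device_rows$mu[r]
        disp <- device_rows$disp[r]
        dev_values[[r]] <- switch(device_rows$scale_type[r],
          linear = mu + disp * u,
          # clock times come at minute resolution from the device
          circular_minutes = round(mu + disp * u) %% 1440,
          count = pmax(0, round(mu * exp(disp * u)))
        )
      }
      lens <- lengths(sched_list)
      n_dev <- sum(lens)
      dev <- tibble::new_tibble(list(
        patient_id = rep(pid, n_dev),
        metric = rep(device_rows$metric, lens),
        source = rep(device_rows$source, lens),
        period = rep(device_rows$period, lens),
        scale_type = rep(device_rows$scale_type, lens),
        date = dates[unlist(sched_list)],
        value = unlist(dev_values)
      ), nrow = n_dev)

      # survey items (latent values binned at fixed cut points) and their
      # summary scores (item sums per scheduled day)
      srv_parts <- list()
      sum_parts <- list()
      for (per in unique(item_rows$period)) {
        its <- item_rows$metric[item_rows$period == per]
        d <- schedule_days(per, n_days)
        vals <- matrix(
          findInterval(U[channel_id(its, per), d, drop = FALSE],
                       ordinal_cuts),
          nrow = length(its)
        )
        n_it <- length(its) * length(d)
        srv_parts[[per]] <- tibble::new_tibble(list(
          patient_id = rep(pid, n_it),
          metric = rep(its, each = length(d)),
          source = rep("survey", n_it),
          period = rep(per, n_it),
          scale_type = rep("ordinal", n_it),
          date = rep(dates[d], length(its)),
          value = as.numeric(t(vals))
        ), nrow = n_it)
        summ <- summary_rows$metric[summary_rows$period == per]
        if (length(summ) && length(its)) {
          nd <- length(d)
          sum_parts[[per]] <- tibble::new_tibble(list(
            patient_id = rep(pid, nd),
            metric = rep(summ, nd),
            source = rep("survey", nd),
            period = rep(per, nd),
            scale_type = rep("linear", nd),
            date = dates[d],
            value = colSums(vals)
          ), nrow = nd)
        }
      }

      metrics_by_patient[[i]] <-
        dplyr::bind_rows(c(list(dev), unname(srv_parts), unname(sum_parts)))
      visits_by_patient[[i]] <- simulate_visits(
        pid, U, config, dates, metrics_by_patient[[i]]
      )
    }
    list(
      metrics = dplyr::bind_rows(metrics_by_patient) %>%
        arrange(.data$patient_id, .data$source, .data$period,
                .data$metric, .data$date),
      visits = dplyr::bind_rows(visits_by_patient) %>%
        arrange(.data$patient_id, .data$date)
    )
  })

  metrics <- out$metrics
  visits <- out$visits
  if (!is.null(config$relapse)) {
    injected <- inject_relapse(metrics, visits, config$relapse,
                               start_date = config$start_date)
    metrics <- injected$metrics
    visits <- injected$visits
  }
  if (config$wear_prob < 1 || config$survey_response_prob < 1) {
    metrics <- apply_missingness(
      metrics,
      wear_prob = config$wear_prob,
      seed = derive_seed(config$seed, "missingness"),
      response_prob = config$survey_response_prob
    )
  }

  truth <- list(
    icc = sb^2 / (sb^2 + se^2),
    sigma_b = sb,
    sigma_e = se,
    cross_corr = config$cross_corr,
    channels = ids,
    relapse = if (is.null(config$relapse)) NULL else unclass(config$relapse),
    wear_prob = config$wear_prob,
    survey_response_prob = config$survey_response_prob,
    seed = config$seed,
    start_date = config$start_date,
    generator_note = paste(
      "All distributional choices are synthetic stand-ins;",
      "the study's device-metric distributions are not publicly deposited."
    )
  )
  structure(list(metrics = metrics, visits = visits, truth = truth),
            class = "psymon_cohort")
}

simulate_visits <- function(pid, U, config, dates, patient_metrics) {
  n_days <- config$observation_days
  sched <- config$visit_schedule
  day_of <- function(scale) seq(sched[[scale]], n_days, by = sched[[scale]])
  visit_days <- sort(unique(unlist(lapply(names(sched), day_of))))

  nv <- length(visit_days)
  cols <- list(patient_id = rep(pid, nv), date = dates[visit_days])
  put <- function(cols, name, days, values) {
    x <- rep(NA_real_, nv)
    x[match(days, visit_days)] <- values
    cols[[name]] <- x
    cols
  }

  # PANSS: 30 items driven by the scale latent plus item-level noise
  pd <- day_of("panss")
  u_p <- U["panss", pd]
  lam <- panss_item_loading
  item_noise <- matrix(rnorm(30 * length(pd)), nrow = 30)
  items <- 1 + matrix(
    findInterval(lam * rep(u_p, each = 30) + sqrt(1 - lam^2) * item_noise,
                 panss_item_cuts),
    nrow = 30
  )
  for (j in seq_along(panss_item_cols)) {
    cols <- put(cols, panss_item_cols[j], pd, items[j, ])
  }
  cols <- put(cols, "panss_total", pd, colSums(items))

  psqi_days <- day_of("psqi")
  comps <- vapply(1:7, function(k) {
    as.numeric(findInterval(U[paste0("psqi_c", k), psqi_days],
                            psqi_component_cuts))
  }, numeric(length(psqi_days)))
  comps <- matrix(comps, ncol = 7)
  for (k in 1:7) cols <- put(cols, paste0("psqi_c", k), psqi_days, comps[, k])
  cols <- put(cols, "psqi_global", psqi_days, rowSums(comps))

  ypas_days <- day_of("ypas")
  ypas_defs <- list(
    ypas_global = 50 + 15 * U["ypas_global", ypas_days],
    ypas_vigorous = pmax(0, 12 + 8 * U["ypas_vigorous", ypas_days]),
    ypas_leisure_walking = pmax(0, 25 + 8 * U["ypas_leisure_walking", ypas_days]),
    ypas_moving = pmax(0, 12 + 4 * U["ypas_moving", ypas_days]),
    ypas_standing = pmax(0, 8 + 3 * U["ypas_standing", ypas_days]),
    ypas_sitting = pmax(0, 4 + 1.5 * U["ypas_sitting", ypas_days])
  )
  for (nm in names(ypas_defs)) cols <- put(cols, nm, ypas_days, ypas_defs[[nm]])

  scalars <- list(
    bprs_total = function(d) round(37 + 6 * U["bprs_total", d]),
    cgi_s = function(d) pmin(7, pmax(1, round(4 + 1.3 * U["cgi_s", d]))),
    cds_total = function(d) pmax(0, round(3 + 2.5 * U["cds_total", d])),
    ymrs_total = function(d) pmax(0, round(4 + 3 * U["ymrs_total", d]))
  )
  scalar_scale <- c(bprs_total = "bprs", cgi_s = "cgi_s",
                    cds_total = "cds", ymrs_total = "ymrs")
  for (col in names(scalars)) {
    d <- day_of(scalar_scale[[col]])
    cols <- put(cols, col, d, scalars[[col]](d))
  }
  v <- tibble::new_tibble(cols, nrow = nv)

  # survey summaries observed at the visit: mean over the prior two weeks
  window_mean <- function(metric, visit_date) {
    sel <- patient_metrics$metric == metric
    sd_ <- patient_metrics$date[sel]
    sv <- patient_metrics$value[sel]
    inw <- sd_ > visit_date - 14 & sd_ <= visit_date
    if (!any(inw)) NA_real_ else mean(sv[inw])
  }
  v$survey_bidaily <- vapply(v$date, function(d) {
    window_mean("bidaily_summary", d)
  }, numeric(1))
  v$survey_weekly <- vapply(v$date, function(d) {
    window_mean("weekly_summary", d)
  }, numeric(1))
  v$med_change <- FALSE
  v
}
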