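#' Three-panel monitor plot for one metric
#'
#' Replicates the monitor's diagnostic layout for a single patient-metric
#' stream: daily values with point-outlier alerts, the 2-week moving mean
#' with mean-shift flags, and the moving variance with variance-shift
#' flags; the baseline period is shaded and the baseline norm drawn as a
#' reference line.
#'
#' @param object A `psymon_monitor` (see [monitor_patient()]).
#' @param metric Metric to plot.
#' @param period Period of the metric (needed when a metric exists in both
#'   daily and nightly form).
#' @param ... Unused.
#' @return A ggplot object (faceted panels).
#' @exportS3Method ggplot2::autoplot
autoplot.psymon_monitor <- function(object, metric,
                                    period = NULL, ...) {
  keys <- names(object$series)
  want <- if (is.null(period)) {
    keys[startsWith(keys, paste0(metric, "."))]
  } else {
    intersect(keys, paste(metric, period, sep = "."))
  }
  if (length(want) == 0) {
    abort(paste0("metric '", metric, "' is not among the monitored series"))
  }
  s <- object$series[[want[1]]]
  norm <- s$norm
  daily <- s$data %>%
    mutate(panel = "daily value", y = monitor_scale(.data$value, norm))
  mw <- s$window_stats %>%
    mutate(panel = "moving mean (2 wk)", y = .data$mean)
  mv <- s$window_stats %>%
    mutate(panel = "moving variance (2 wk)", y = .data$variance)
  dat <- dplyr::bind_rows(
    daily[, c("date", "y", "panel")],
    mw[, c("date", "y", "panel")],
    mv[, c("date", "y", "panel")]
  )
  al <- object$alerts %>%
    filter(.data$metric == s$metric, .data$period == s$period) %>%
    mutate(panel = dplyr::case_match(
      .data$kind,
      "point_outlier" ~ "daily value",
      "mean_shift" ~ "moving mean (2 wk)",
      "slope_change" ~ "moving mean (2 wk)",
      "variance_shift" ~ "moving variance (2 wk)"
    ))
  al <- al %>%
    left_join(dat, by = c("date", "panel")) %>%
    filter(!is.na(.data$y))
  ref <- tibble(
    panel = c("daily value", "moving mean (2 wk)", "moving variance (2 wk)"),
    ref = c(norm$mean, norm$mean, norm$variance)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$y)) +
    ggplot2::annotate(
      "rect",
      xmin = norm$interval[1], xmax = norm$interval[2],
      ymin = -Inf, ymax = Inf, alpha = 0.08
    ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(
      data = ref, ggplot2::aes(yintercept = .data$ref), linetype = 2
    ) +
    ggplot2::geom_point(
      data = al,
      ggplot2::aes(shape = .data$kind, colour = .data$kind), size = 2.2
    ) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      title = paste0(object$patient_id, ": ", s$metric, " (", s$period, ")"),
      x = NULL, y = NULL, colour = "alert", shape = "alert"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise association table
#'
#' @param assoc Output of [association_matrix()].
#' @return A ggplot tile plot: coefficient fill, "nc" for non-converged
#'   pairs, stars on significant associations.
#' @export
plot_association_matrix <- function(assoc) {
  a <- assoc %>%
    mutate(label = ifelse(
      .data$converged,
      paste0(
        sprintf("%.2f", .data$coefficient),
        ifelse(.data$significant, "*", "")
      ),
      "nc"
    ))
  ggplot2::ggplot(
    a,
    ggplot2::aes(x = .data$predictor, y = .data$response,
                 fill = .data$coefficient)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "coef") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
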