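#' Configuration of the individualized streaming monitor
#'
#' Tunables of the statistical-process-control monitor: the first
#' `baseline_days` of each stream establish the patient's own norm; daily
#' values more than `outlier_k` baseline SDs from the norm raise point
#' outliers; a trailing moving window of `window_days` is tested against
#' the baseline mean (Welch t) and variance (F ratio) at level `alpha`;
#' and the least-squares slope over the trailing `slope_interval_days` is
#' tested against zero at the same level.
#'
#' @param baseline_days Baseline period length (study rule: the first
#'   month).
#' @param outlier_k Point-outlier threshold in baseline SDs (study rule:
#'   2.5).
#' @param window_days Moving-window length (study rule: 2 weeks).
#' @param alpha Two-sided level for the window and slope tests.
#' @param slope_interval_days Trailing slope interval.
#' @param min_baseline_days Minimum days with data required to fit a
#'   baseline.
#' @return A `psymon_monitor_config` list.
#' @export
monitor_config <- function(baseline_days = 30, outlier_k = 2.5,
                           window_days = 14, alpha = 0.05,
                           slope_interval_days = 14,
                           min_baseline_days = 21) {
  if (outlier_k <= 0) abort("outlier_k must be > 0")
  if (window_days < 3) abort("window_days must be >= 3")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(
    list(
      baseline_days = as.integer(baseline_days),
      outlier_k = outlier_k,
      window_days = as.integer(window_days),
      alpha = alpha,
      slope_interval_days = as.integer(slope_interval_days),
      min_baseline_days = as.integer(min_baseline_days)
    ),
    class = "psymon_monitor_config"
  )
}

#' Construct a baseline norm directly
#'
#' A per-patient, per-metric baseline (mean, variance, number of days)
#' against which streaming alerts are judged. Usually produced by
#' [fit_baseline()]; constructing one directly is useful when the
#' population values are known (e.g. for calibration studies).
#'
#' @param mean Baseline mean (circular mean in minutes for clock metrics).
#' @param variance Baseline variance (> 0).
#' @param n_days Number of baseline days the norm represents.
#' @param metric Metric name.
#' @param scale_type Scale type of the metric.
#' @param interval Length-2 date vector `(start, end]` of the baseline
#'   period, or `NULL` for a synthetic norm.
#' @return A `psymon_baseline` list.
#' @export
baseline_norm <- function(mean, variance, n_days, metric = NA_character_,
                          scale_type = "linear", interval = NULL) {
  if (!is.finite(variance) || variance <= 0) {
    abort("baseline variance must be finite and > 0")
  }
  structure(
    list(metric = metric, scale_type = scale_type, mean = mean,
         variance = variance, n_days = as.integer(n_days),
         interval = interval),
    class = "psymon_baseline"
  )
}

#' Fit a patient's baseline norm from the first weeks of a stream
#'
#' Mean and variance over the baseline interval (the first
#' `config$baseline_days` study days). Clock-time metrics use the circular
#' mean; their variance is computed after unwrapping the minutes into the
#' linear window of width one day centred on the circular mean, which makes
#' the downstream t/F/slope machinery valid locally. The norm is frozen
#' once fitted: it is never re-estimated as the stream evolves.
#'
#' @param dates,values One patient-metric stream.
#' @param config A [monitor_config()].
#' @param scale_type Scale type of the metric.
#' @param start_date Calendar date of study day 1 (defaults to the first
#'   sample).
#' @return A `psymon_baseline`.
#' @export
fit_baseline <- function(dates, values, config = monitor_config(),
                         scale_type = "linear", start_date = min(dates)) {
  end <- as.Date(start_date) + config$baseline_days - 1
  keep <- dates <= end & !is.na(values)
  x <- values[keep]
  if (length(x) < config$min_baseline_days) {
    abort(sprintf(
      "insufficient baseline data: %d day(s) available, %d required",
      length(x), config$min_baseline_days
    ))
  }
  if (scale_type == "circular_minutes") {
    ctr <- circular_mean_minutes(x)
    v <- var(unwrap_minutes(x, ctr))
    m <- ctr
  } else {
    m <- mean(x)
    v <- var(x)
  }
  if (!is.finite(v) || v <= 0) {
    abort("degenerate baseline: zero variance over the baseline interval")
  }
  baseline_norm(
    mean = m, variance = v, n_days = length(x),
    scale_type = scale_type,
    interval = c(as.Date(start_date) - 1, end)
  )
}

post_baseline <- function(dates, norm) {
  if (is.null(norm$interval)) rep(TRUE, length(dates)) else
    dates > norm$interval[2]
}

# Values on the scale the linear tests run on: clock metrics are unwrapped
# into +/- 720 minutes around the baseline circular mean.
monitor_scale <- function(values, norm) {
  if (norm$scale_type == "circular_minutes") {
    unwrap_minutes(values, norm$mean)
  } else {
    values
  }
}

#' Point-outlier alerts against a baseline norm
#'
#' Flags each post-baseline day whose value lies more than
#' `config$outlier_k` baseline SDs from the baseline mean (two-sided;
#' circular distance for clock metrics).
#'
#' @param dates,values One patient-metric stream.
#' @param norm A `psymon_baseline`.
#' @param config A [monitor_config()].
#' @return Tibble of alerts: `date`, `kind`, `statistic` (the z-score),
#'   `threshold`, `direction`.
#' @export
detect_point_outliers <- function(dates, values, norm,
                                  config = monitor_config()) {
  keep <- post_baseline(dates, norm) & !is.na(values)
  d <- dates[keep]
  v <- values[keep]
  dev <- if (norm$scale_type == "circular_minutes") {
    circular_diff_minutes(v, norm$mean)
  } else {
    v - norm$mean
  }
  z <- dev / sqrt(norm$variance)
  hit <- abs(z) > config$outlier_k
  tibble(
    date = d[hit], kind = "point_outlier", statistic = z[hit],
    threshold = config$outlier_k, direction = sign(z[hit])
  )
}

#' Trailing moving-window mean and variance
#'
#' For every post-baseline day `d`, the sample mean and variance over the
#' half-open trailing window `(d - window_days, d]`, emitted only when at
#' least half the window has data (otherwise the day is a gap). Clock
#' metrics are first unwrapped around the baseline circular mean. No value
#' after `d` enters the window for day `d`.
#'
#' @param dates,values One patient-metric stream.
#' @param norm A `psymon_baseline`.
#' @param config A [monitor_config()].
#' @return Tibble: `date`, `mean`, `variance`, `n`.
#' @export
moving_window_stats <- function(dates, values, norm,
                                config = monitor_config()) {
  ok <- !is.na(values)
  dates <- dates[ok]
  v <- monitor_scale(values[ok], norm)
  if (length(dates) == 0) {
    return(tibble(date = as.Date(character()), mean = numeric(),
                  variance = numeric(), n = integer()))
  }
  first <- if (is.null(norm$interval)) min(dates) else norm$interval[2] + 1
  last <- max(dates)
  if (first > last) {
    return(tibble(date = as.Date(character()), mean = numeric(),
                  variance = numeric(), n = integer()))
  }
  w <- config$window_days
  # daily grid back to the earliest sample a window can reach, rolling
  # sums via cumulative sums (centering first for numerical stability)
  grid <- seq(min(min(dates), as.Date(first) - w + 1), last, by = "day")
  idx <- as.integer(dates - grid[1]) + 1
  present <- numeric(length(grid))
  vals <- numeric(length(grid))
  present[idx] <- 1
  ctr <- mean(v)
  vals[idx] <- v - ctr
  cs_n <- cumsum(present)
  cs_v <- cumsum(vals)
  cs_v2 <- cumsum(vals^2)
  at <- as.integer(seq(as.Date(first), last, by = "day") - grid[1]) + 1
  lo <- pmax(at - w, 0)
  roll <- function(cs, hi, lo) cs[hi] - ifelse(lo == 0, 0, cs[lo])
  n <- roll(cs_n, at, lo)
  sv <- roll(cs_v, at, lo)
  sv2 <- roll(cs_v2, at, lo)
  keep <- n >= w / 2
  n <- n[keep]
  m <- sv[keep] / n
  va <- ifelse(n >= 2, pmax(0, (sv2[keep] - n * m^2)) / (n - 1), NA_real_)
  # cancellation residue on a constant window is numerically zero
  va[!is.na(va) & va < 1e-10 * (1 + m^2)] <- 0
  tibble(date = grid[at[keep]], mean = ctr + m, variance = va,
         n = as.integer(n))
}

#' Welch test of the moving-window mean against the baseline
#'
#' For each windowed day, a two-sample Welch t-test comparing the window
#' samples with the baseline samples (summary-statistic form, using the
#' frozen baseline mean/variance/n). Days are tested independently at
#' level `alpha`; under day-to-day autocorrelation the realized flag rate
#' is anti-conservative, which is accepted for an alerting stream.
#'
#' @param window_stats Output of [moving_window_stats()].
#' @param norm A `psymon_baseline`.
#' @param config A [monitor_config()].
#' @return Tibble per windowed day: `date`, `kind`, `statistic`,
#'   `threshold`, `direction`, `p_value`, `flagged`.
#' @export
test_mean_shift <- function(window_stats, norm, config = monitor_config()) {
  ws <- window_stats[window_stats$n >= 2 & !is.na(window_stats$variance), ]
  if (nrow(ws) == 0) {
    return(tibble(date = as.Date(character()), kind = character(),
                  statistic = numeric(), threshold = numeric(),
                  direction = numeric(), p_value = numeric(),
                  flagged = logical()))
  }
  se2 <- ws$variance / ws$n + norm$variance / norm$n_days
  t <- (ws$mean - norm$mean) / sqrt(se2)
  df <- se2^2 / (
    (ws$variance / ws$n)^2 / (ws$n - 1) +
      (norm$variance / norm$n_days)^2 / (norm$n_days - 1)
  )
  p <- 2 * pt(-abs(t), df)
  tibble(
    date = ws$date, kind = "mean_shift", statistic = t,
    threshold = qt(1 - config$alpha / 2, df), direction = sign(t),
    p_value = p, flagged = p < config$alpha
  )
}

#' F test of the moving-window variance against the baseline
#'
#' For each windowed day, the variance ratio window/baseline is referred
#' to an F distribution with `n_window - 1` and `n_baseline - 1` degrees
#' of freedom, two-sided at `alpha`. A zero-variance window gives a ratio
#' of 0 and is flagged as a (degenerate) downward variance shift.
#'
#' @inheritParams test_mean_shift
#' @return Tibble per windowed day, as [test_mean_shift()].
#' @export
test_variance_shift <- function(window_stats, norm,
                                config = monitor_config()) {
  ws <- window_stats[window_stats$n >= 2 & !is.na(window_stats$variance), ]
  if (nrow(ws) == 0) {
    return(tibble(date = as.Date(character()), kind = character(),
                  statistic = numeric(), threshold = numeric(),
                  direction = numeric(), p_value = numeric(),
                  flagged = logical()))
  }
  f <- ws$variance / norm$variance
  df1 <- ws$n - 1
  df2 <- norm$n_days - 1
  p <- 2 * pmin(pf(f, df1, df2), 1 - pf(f, df1, df2))
  tibble(
    date = ws$date, kind = "variance_shift", statistic = f,
    threshold = qf(1 - config$alpha / 2, df1, df2),
    direction = sign(f - 1), p_value = p, flagged = p < config$alpha
  )
}

#' Trailing-slope trend test
#'
#' For each post-baseline day, the least-squares slope of the values over
#' the trailing `slope_interval_days` is tested against zero via its
#' t-statistic (two-sided at `alpha`). At least 3 points are required; a
#' noiseless ramp gives an infinite statistic and is flagged.
#'
#' @param dates,values One patient-metric stream.
#' @param norm A `psymon_baseline`.
#' @param config A [monitor_config()].
#' @return Tibble per evaluable day: `date`, `kind`, `statistic`,
#'   `threshold`, `direction`, `p_value`, `flagged`.
#' @export
test_slope_change <- function(dates, values, norm,
                              config = monitor_config()) {
  ok <- !is.na(values)
  dates <- dates[ok]
  v <- monitor_scale(values[ok], norm)
  empty <- tibble(date = as.Date(character()), kind = character(),
                  statistic = numeric(), threshold = numeric(),
                  direction = numeric(), p_value = numeric(),
                  flagged = logical())
  if (length(dates) == 0) return(empty)
  first <- if (is.null(norm$interval)) min(dates) else norm$interval[2] + 1
  last <- max(dates)
  if (first > last) return(empty)
  L <- config$slope_interval_days
  # rolling regression sums on a daily grid (x = day offset from grid
  # origin, y centered for numerical stability)
  grid <- seq(min(min(dates), as.Date(first) - L + 1), last, by = "day")
  idx <- as.integer(dates - grid[1]) + 1
  G <- length(grid)
  present <- numeric(G)
  y0 <- numeric(G)
  present[idx] <- 1
  ctr <- mean(v)
  y0[idx] <- v - ctr
  xg <- as.numeric(seq_len(G)) * present
  cs <- function(z) cumsum(z)
  cs_n <- cs(present); cs_x <- cs(xg); cs_x2 <- cs(xg^2)
  cs_y <- cs(y0); cs_y2 <- cs(y0^2); cs_xy <- cs(xg * y0)
  at <- as.integer(seq(as.Date(first), last, by = "day") - grid[1]) + 1
  lo <- pmax(at - L, 0)
  roll <- function(csum) csum[at] - ifelse(lo == 0, 0, csum[lo])
  n <- roll(cs_n)
  sx <- roll(cs_x); sx2 <- roll(cs_x2)
  sy <- roll(cs_y); sy2 <- roll(cs_y2); sxy <- roll(cs_xy)
  sxx_c <- sx2 - sx^2 / n
  keep <- n >= 3 & sxx_c > 1e-12
  if (!any(keep)) return(empty)
  n <- n[keep]
  sxx_c <- sxx_c[keep]
  sxy_c <- sxy[keep] - sx[keep] * sy[keep] / n
  syy_c <- pmax(0, sy2[keep] - sy[keep]^2 / n)
  b <- sxy_c / sxx_c
  sse <- pmax(0, syy_c - b * sxy_c)
  s2 <- sse / (n - 2)
  t <- ifelse(s2 <= 1e-300, ifelse(b == 0, 0, sign(b) * Inf),
              b / sqrt(s2 / sxx_c))
  p <- 2 * pt(-abs(t), n - 2)
  tibble(date = grid[at[keep]], kind = "slope_change", statistic = t,
         threshold = qt(1 - config$alpha / 2, n - 2),
         direction = sign(b), p_value = p, flagged = p < config$alpha)
}

#' Monitor every stream of one patient
#'
#' Runs the full alerting stack (baseline fit, point outliers, moving
#' window mean/variance tests, trailing slope test) on every metric stream
#' of one patient and collects the union of alerts. Metrics whose baseline
#' cannot be fitted (too few baseline days, zero variance) are listed as
#' skipped rather than failing the run. The returned object carries the
#' daily values, moving statistics and flags per metric, ready for the
#' three-panel monitor plot ([autoplot.psymon_monitor()]).
#'
#' @param metrics Long metrics tibble of a single patient.
#' @param config A [monitor_config()].
#' @param start_date Calendar date of study day 1.
#' @return A `psymon_monitor` object: `alerts` tibble (`patient_id`,
#'   `metric`, `period`, `date`, `kind`, `statistic`, `threshold`,
#'   `direction`), `skipped` tibble, and per-metric `series` detail.
#' @export
monitor_patient <- function(metrics, config = monitor_config(),
                            start_date = min(metrics$date)) {
  pid <- unique(metrics$patient_id)
  if (length(pid) != 1) abort("monitor_patient expects exactly one patient")
  groups <- metrics %>%
    group_by(.data$metric, .data$period, .data$scale_type) %>%
    tidyr::nest() %>%
    ungroup()
  alerts <- list()
  series <- list()
  skipped <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    d <- g$data[[1]] %>% arrange(.data$date)
    norm <- tryCatch(
      fit_baseline(d$date, d$value, config, scale_type = g$scale_type,
                   start_date = start_date),
      error = function(e) e
    )
    key <- paste(g$metric, g$period, sep = ".")
    if (inherits(norm, "error")) {
      skipped[[key]] <- tibble(metric = g$metric, period = g$period,
                               reason = conditionMessage(norm))
      next
    }
    po <- detect_point_outliers(d$date, d$value, norm, config)
    ws <- moving_window_stats(d$date, d$value, norm, config)
    ms <- test_mean_shift(ws, norm, config)
    vs <- test_variance_shift(ws, norm, config)
    sl <- test_slope_change(d$date, d$value, norm, config)
    flagged <- dplyr::bind_rows(
      po,
      ms[ms$flagged, c("date", "kind", "statistic", "threshold", "direction")],
      vs[vs$flagged, c("date", "kind", "statistic", "threshold", "direction")],
      sl[sl$flagged, c("date", "kind", "statistic", "threshold", "direction")]
    )
    if (nrow(flagged)) {
      alerts[[key]] <- flagged %>%
        mutate(patient_id = pid, metric = g$metric, period = g$period,
               .before = 1)
    }
    series[[key]] <- list(
      metric = g$metric, period = g$period, norm = norm,
      data = d, window_stats = ws, mean_tests = ms, variance_tests = vs,
      slope_tests = sl
    )
  }
  structure(
    list(
      patient_id = pid,
      config = config,
      alerts = if (length(alerts)) dplyr::bind_rows(alerts) else
        tibble(patient_id = character(), metric = character(),
               period = character(), date = as.Date(character()),
               kind = character(), statistic = numeric(),
               threshold = numeric(), direction = numeric()),
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
        tibble(metric = character(), period = character(),
               reason = character()),
      series = series
    ),
    class = "psymon_monitor"
  )
}

#' @export
print.psymon_monitor <- function(x, ...) {
  cat("Streaming monitor for patient", x$patient_id, "\n")
  cat(" metrics monitored:", length(x$series),
      "| skipped:", nrow(x$skipped), "\n")
  if (nrow(x$alerts)) {
    print(count(x$alerts, .data$kind))
  } else {
    cat(" no alerts\n")
  }
  invisible(x)
}
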