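#' Circular statistics for clock-time metrics
#'
#' Clock times (sleep start, rest start) live on a 1440-minute circle, so a
#' night that starts at 23:30 and one that starts at 00:30 average to
#' midnight, not midday. These helpers convert minutes after midnight to
#' angles, average on the circle and report dispersion via the mean
#' resultant length \eqn{R}: circular SD \eqn{= \sqrt{-2\log R}} (radians),
#' rescaled to minutes.
#'
#' @param minutes Numeric vector of minutes after midnight (any real values;
#'   reduced mod 1440).
#' @return `circular_mean_minutes()` the mean direction in `[0, 1440)`;
#'   `circular_sd_minutes()` the circular SD in minutes (0 for a single
#'   point; `Inf` when the resultant length is 0).
#' @examples
#' circular_mean_minutes(c(23.5 * 60, 0.5 * 60)) # midnight, not noon
#' @export
circular_mean_minutes <- function(minutes) {
  minutes <- minutes[!is.na(minutes)]
  if (length(minutes) == 0) return(NA_real_)
  theta <- minutes / 1440 * 2 * pi
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  out <- (m / (2 * pi) * 1440) %% 1440
  if (1440 - out < 1e-9) out <- 0 # guard the wrap point
  out
}

#' @rdname circular_mean_minutes
#' @export
circular_sd_minutes <- function(minutes) {
  minutes <- minutes[!is.na(minutes)]
  if (length(minutes) == 0) return(NA_real_)
  theta <- minutes / 1440 * 2 * pi
  r <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r)) / (2 * pi) * 1440
}

# Signed shortest distance a -> b on the 1440-minute circle, in (-720, 720].
circular_diff_minutes <- function(a, b) {
  d <- (a - b) %% 1440
  ifelse(d > 720, d - 1440, d)
}

# Unwrap clock values into the linear window (center - 720, center + 720],
# so locally-linear tests (t, F, slope) are valid near the baseline mean.
unwrap_minutes <- function(minutes, center) {
  center + circular_diff_minutes(minutes, center)
}

#' Parse and format "HH:MM" clock times
#'
#' Serialization helpers for circular metrics: CSV files carry clock times
#' as `"HH:MM"`; internally they are minutes after midnight.
#'
#' @param x Character vector of `"HH:MM"` strings.
#' @param minutes Numeric vector of minutes in `[0, 1440)`.
#' @return Minutes after midnight, or `"HH:MM"` strings.
#' @export
parse_hhmm <- function(x) {
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x) | is.na(x)
  if (!all(ok)) {
    abort(paste0(
      "malformed clock time(s): ",
      paste(unique(x[!ok])[seq_len(min(3, sum(!ok)))], collapse = ", "),
      " (expected HH:MM with HH in 00-23)"
    ))
  }
  out <- rep(NA_real_, length(x))
  has <- !is.na(x)
  out[has] <- as.numeric(substr(x[has], 1, 2)) * 60 +
    as.numeric(substr(x[has], 4, 5))
  out
}

#' @rdname parse_hhmm
#' @export
format_hhmm <- function(minutes) {
  m <- round(minutes) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
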