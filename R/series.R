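#' Create a sampled time series
#'
#' Light container for a sampled scalar signal: a data frame with columns
#' `time_s` and `value`, carrying the physical unit and (optionally) the
#' cycle period as attributes. All waveform, Windkessel and flow-split
#' functions consume and return this shape.
#'
#' @param time numeric vector of sample times (s), strictly increasing.
#' @param value numeric vector of samples, same length as `time`.
#' @param unit character unit label carried as metadata (e.g. "m/s", "ml/s",
#'   "mmHg").
#' @param period cycle period in seconds, or `NA` for aperiodic signals.
#' @return a data frame of class `hemo_series` with columns `time_s`, `value`.
#' @examples
#' s <- hemo_series(seq(0, 1, 0.1), sin(seq(0, 1, 0.1)), unit = "m/s")
#' series_unit(s)
#' @export
hemo_series <- function(time, value, unit = "", period = NA_real_) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value))
    stop("`time` and `value` must have equal length", call. = FALSE)
  if (length(time) >= 2 && any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (anyNA(time) || anyNA(value))
    stop("time series must not contain NA", call. = FALSE)
  out <- data.frame(time_s = time, value = value)
  attr(out, "unit") <- as.character(unit)
  attr(out, "period") <- as.numeric(period)
  class(out) <- c("hemo_series", "data.frame")
  out
}

#' @rdname hemo_series
#' @param x a `hemo_series`.
#' @export
series_unit <- function(x) attr(x, "unit")

#' @rdname hemo_series
#' @export
series_period <- function(x) attr(x, "period")

#' @export
print.hemo_series <- function(x, ...) {
  unit <- series_unit(x)
  cat(sprintf("<hemo_series> %d samples over [%g, %g] s%s\n",
              nrow(x), x$time_s[1], x$time_s[nrow(x)],
              if (nzchar(unit)) paste0(" [", unit, "]") else ""))
  if (!is.na(series_period(x)))
    cat(sprintf("  cycle period: %g s\n", series_period(x)))
  cat(sprintf("  range: [%g, %g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.hemo_series <- function(x, ..., xlab = "time (s)", ylab = NULL, type = "l") {
  if (is.null(ylab)) {
    unit <- series_unit(x)
    ylab <- if (nzchar(unit)) paste0("value (", unit, ")") else "value"
  }
  plot(x$time_s, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Composite trapezoid integral of a sampled signal; the workhorse quadrature
# for every time average in the package (robust on uniform and ragged grids).
trapz <- function(time, value) {
  n <- length(time)
  if (n < 2) return(0)
  sum((value[-1] + value[-n]) * diff(time)) / 2
}

# Restrict a series to a closed time window [t0, t1] (samples inside only).
window_series <- function(x, t0, t1) {
  keep <- x$time_s >= t0 - 1e-12 & x$time_s <= t1 + 1e-12
  hemo_series(x$time_s[keep], x$value[keep], unit = series_unit(x),
              period = series_period(x))
}
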