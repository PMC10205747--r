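#' Patient cardiac timing for the half-sine inlet waveform
#'
#' Bundles the three quantities that define an idealised half-sine systolic
#' ejection profile: cycle period \eqn{T}, systolic ejection duration
#' \eqn{D}, and peak inlet velocity \eqn{V_0}. Defaults are the post-TEVAR
#' Doppler-derived patient values used throughout the package
#' (\eqn{V_0 = 96.1} cm/s, \eqn{D = 0.273} s, \eqn{T = 0.731} s).
#'
#' Some sources express the ejection time as a fraction of the cycle rather
#' than a duration; pass `ejection_fraction` instead of `ejection_duration`
#' to use that convention (the duration is then `ejection_fraction * period`).
#'
#' @param period cardiac cycle length in seconds.
#' @param ejection_duration systolic ejection duration in seconds.
#' @param peak_velocity peak inlet velocity in m/s (`peak_velocity_cms`
#'   accepts cm/s instead).
#' @param ejection_fraction alternative to `ejection_duration`: ejection time
#'   as a fraction of the period.
#' @param peak_velocity_cms alternative to `peak_velocity`: peak velocity in
#'   cm/s.
#' @return an object of class `cardiac_timing`.
#' @examples
#' ct <- cardiac_timing()
#' inlet_velocity(ct$ejection_duration / 2, ct)  # peak, 0.961 m/s
#' @export
cardiac_timing <- function(period = 0.731, ejection_duration = 0.273,
                           peak_velocity = 0.961,
                           ejection_fraction = NULL,
                           peak_velocity_cms = NULL) {
  if (!is.null(ejection_fraction)) {
    if (ejection_fraction <= 0 || ejection_fraction >= 1)
      stop("`ejection_fraction` must lie in (0, 1)", call. = FALSE)
    ejection_duration <- ejection_fraction * period
  }
  if (!is.null(peak_velocity_cms)) peak_velocity <- peak_velocity_cms / 100
  if (!is.finite(period) || period <= 0)
    stop("`period` must be a positive duration in seconds", call. = FALSE)
  if (!is.finite(ejection_duration) || ejection_duration <= 0 ||
      ejection_duration >= period)
    stop("`ejection_duration` must satisfy 0 < D < period", call. = FALSE)
  if (!is.finite(peak_velocity) || peak_velocity <= 0)
    stop("`peak_velocity` must be positive", call. = FALSE)
  structure(list(period = period, ejection_duration = ejection_duration,
                 peak_velocity = peak_velocity),
            class = "cardiac_timing")
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat("<cardiac_timing>\n")
  cat(sprintf("  period T           : %g s (%.0f bpm)\n", x$period, 60 / x$period))
  cat(sprintf("  ejection duration D: %g s\n", x$ejection_duration))
  cat(sprintf("  peak velocity V0   : %g m/s\n", x$peak_velocity))
  invisible(x)
}

#' Half-sine inlet velocity
#'
#' Evaluates the idealised systolic inlet velocity
#' \deqn{V(t) = V_0 \sin(\pi \tilde t / D) \ \mathrm{for}\ 0 < \tilde t < D,
#'   \quad 0 \ \mathrm{otherwise},}
#' where \eqn{\tilde t = t \bmod T}. The signal is continuous at the ends of
#' the ejection window and identically zero in diastole.
#'
#' @param t time(s) in seconds; any real values, reduced modulo the period.
#' @param timing a [cardiac_timing()].
#' @return inlet velocity in m/s, same length as `t`.
#' @export
inlet_velocity <- function(t, timing = cardiac_timing()) {
  stopifnot(inherits(timing, "cardiac_timing"))
  tt <- t %% timing$period
  d <- timing$ejection_duration
  v <- ifelse(tt < d, timing$peak_velocity * sin(pi * tt / d), 0)
  # sin() can go a hair negative at the window edge through roundoff
  pmax(v, 0)
}

#' Sample the inlet waveform on a uniform grid
#'
#' @param timing a [cardiac_timing()].
#' @param dt sampling step in seconds (default 0.002 s, the solver step the
#'   package mirrors).
#' @param n_cycles number of cardiac cycles to cover (>= 1). The grid is
#'   uniform with the endpoint `n_cycles * period` always included.
#' @return a [hemo_series()] of velocity in m/s, flagged with the cycle
#'   period.
#' @export
sample_waveform <- function(timing = cardiac_timing(), dt = 0.002, n_cycles = 1) {
  stopifnot(inherits(timing, "cardiac_timing"))
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  if (dt >= timing$ejection_duration)
    warning("dt >= ejection duration: systolic peak will be under-resolved",
            call. = FALSE)
  t_end <- n_cycles * timing$period
  tt <- seq(0, t_end, by = dt)
  if (tt[length(tt)] < t_end - 1e-12) tt <- c(tt, t_end)
  hemo_series(tt, inlet_velocity(tt, timing), unit = "m/s",
              period = timing$period)
}

#' Volumetric inlet flow from the velocity waveform
#'
#' Converts velocity to volumetric flow under a plug (flat) profile,
#' \eqn{Q(t) = V(t) A}. The inlet cross-section area is a configuration
#' parameter; the default 4.9 cm^2 is a typical adult ascending-aorta lumen.
#'
#' @inheritParams sample_waveform
#' @param inlet_area inlet cross-section area in m^2.
#' @param unit output unit, `"m3/s"` or `"ml/s"`.
#' @return a [hemo_series()] of volumetric flow.
#' @export
flow_waveform <- function(timing = cardiac_timing(), inlet_area = 4.9e-4,
                          dt = 0.002, n_cycles = 1, unit = c("m3/s", "ml/s")) {
  unit <- match.arg(unit)
  if (!is.finite(inlet_area) || inlet_area <= 0)
    stop("`inlet_area` must be a positive area in m^2", call. = FALSE)
  v <- sample_waveform(timing, dt = dt, n_cycles = n_cycles)
  q <- v$value * inlet_area
  if (unit == "ml/s") q <- q * 1e6
  hemo_series(v$time_s, q, unit = unit, period = timing$period)
}
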