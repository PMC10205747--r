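#' Wall-shear-stress indices: TAWSS, OSI, HOLMES
#'
#' Per-node indices over one cardiac cycle of a wall-shear vector series
#' \eqn{\vec\tau(t)}:
#' \deqn{\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\vec\tau|\,dt, \qquad
#'   \mathrm{OSI} = \frac{1}{2}\left(1 -
#'   \frac{\left|\frac{1}{T}\int_0^T \vec\tau\,dt\right|}{\mathrm{TAWSS}}\right),
#'   \qquad \mathrm{HOLMES} = \mathrm{TAWSS}\,(0.5 - \mathrm{OSI}).}
#' OSI is 0 for steady unidirectional shear and 0.5 for fully reversing,
#' zero-mean shear; HOLMES is low where shear is weak and oscillatory — the
#' wall regions flagged as atherosclerosis/thrombus prone. All integrals are
#' composite trapezoids on the stored time grid (robust on uniform and
#' ragged grids alike). When the series covers several whole cycles, the
#' last cycle is used.
#'
#' @param wall a wall-shear [field_series()] (Pa) spanning at least one
#'   cycle.
#' @param period cycle period, s; defaults to the field's own period.
#' @return `tawss()` and `osi()` return per-node numeric vectors;
#'   `holmes()` the element-wise product above.
#' @name wss_indices
NULL

# extract the last full cycle [t_end - period, t_end]; errors if the series
# is shorter than one period
last_cycle <- function(field, period) {
  if (is.null(period) || is.na(period)) period <- field$period
  if (is.null(period) || is.na(period))
    stop("no cycle period available: pass `period`", call. = FALSE)
  t_end <- field$times[length(field$times)]
  span <- t_end - field$times[1]
  if (span < period - 1e-9)
    stop(sprintf("series spans %.4g s, shorter than one period (%.4g s)",
                 span, period), call. = FALSE)
  keep <- field$times >= t_end - period - 1e-9
  list(times = field$times[keep],
       vectors = field$vectors[keep, , , drop = FALSE],
       period = period)
}

#' @rdname wss_indices
#' @export
tawss <- function(wall, period = NULL) {
  stopifnot(inherits(wall, "field_series"))
  if (wall$kind != "wall_shear")
    stop("`wall` must be a wall_shear field", call. = FALSE)
  cyc <- last_cycle(wall, period)
  mags <- sqrt(apply(cyc$vectors^2, c(1, 2), sum))   # n_times x n_points
  apply(mags, 2, function(m) trapz(cyc$times, m)) / cyc$period
}

#' @rdname wss_indices
#' @param eps nodes with TAWSS below `eps` (Pa) are returned as OSI = 0: the
#'   index is 0/0 there and no shear means no oscillation to report.
#' @export
osi <- function(wall, period = NULL, eps = 1e-12) {
  stopifnot(inherits(wall, "field_series"))
  if (wall$kind != "wall_shear")
    stop("`wall` must be a wall_shear field", call. = FALSE)
  cyc <- last_cycle(wall, period)
  ta <- tawss(wall, period)
  mean_vec <- sapply(1:3, function(a)
    apply(cyc$vectors[, , a, drop = FALSE], 2,
          function(v) trapz(cyc$times, v))) / cyc$period
  mean_vec <- matrix(mean_vec, ncol = 3)
  mag_mean <- sqrt(rowSums(mean_vec^2))
  out <- numeric(length(ta))
  live <- ta >= eps
  out[live] <- 0.5 * (1 - mag_mean[live] / ta[live])
  # |mean vector| <= mean |vector| analytically; clamp roundoff only
  pmin(pmax(out, 0), 0.5)
}

#' @rdname wss_indices
#' @param tawss_map,osi_map aligned per-node vectors from [tawss()] and
#'   [osi()].
#' @export
holmes <- function(tawss_map, osi_map) {
  if (length(tawss_map) != length(osi_map))
    stop("TAWSS and OSI maps are not aligned", call. = FALSE)
  tawss_map * (0.5 - osi_map)
}

#' Per-node index map for a wall-shear series
#'
#' Convenience wrapper computing TAWSS, OSI and HOLMES together.
#'
#' @inheritParams wss_indices
#' @return an object of class `wss_index_map`: list with `points`, `tawss`,
#'   `osi`, `holmes`, `cycle_period`.
#' @export
wss_index_map <- function(wall, period = NULL) {
  ta <- tawss(wall, period)
  os <- osi(wall, period)
  per <- if (is.null(period) || is.na(period)) wall$period else period
  structure(list(points = wall$points, tawss = ta, osi = os,
                 holmes = holmes(ta, os), cycle_period = per),
            class = "wss_index_map")
}

#' @export
print.wss_index_map <- function(x, ...) {
  cat(sprintf("<wss_index_map> %d nodes, cycle %g s\n",
              length(x$tawss), x$cycle_period))
  cat(sprintf("  TAWSS : [%.4g, %.4g] Pa\n", min(x$tawss), max(x$tawss)))
  cat(sprintf("  OSI   : [%.4g, %.4g]\n", min(x$osi), max(x$osi)))
  cat(sprintf("  HOLMES: [%.4g, %.4g] Pa\n", min(x$holmes), max(x$holmes)))
  invisible(x)
}

#' Node-wise percent difference between two index maps
#'
#' Compares two aligned per-node fields (for instance HOLMES from a
#' compliant-wall run against a rigid-wall run) as
#' \eqn{100\,(a - b)/\mathrm{denom}}. Nodes whose denominator magnitude falls
#' below `mask_eps` are masked out of the summary rather than producing
#' blow-ups. The summary reports the fraction of unmasked nodes whose
#' absolute change exceeds 5, 10 and 20 percent — the three colour scales
#' used when mapping wall-motion sensitivity.
#'
#' @param field_a,field_b aligned per-node numeric vectors.
#' @param denominator which field normalises the difference: `"b"` (default;
#'   e.g. the rigid-wall reference) or `"a"`.
#' @param mask_eps denominator magnitude below which a node is masked (same
#'   units as the fields).
#' @return list of class `percent_diff_map`: `percent` (per-node, NA where
#'   masked), `masked` (logical), and `summary` (fractions of nodes with
#'   |change| > 5 / 10 / 20 %).
#' @export
percent_difference_map <- function(field_a, field_b,
                                   denominator = c("b", "a"),
                                   mask_eps = 1e-12) {
  denominator <- match.arg(denominator)
  if (length(field_a) != length(field_b))
    stop("fields are not aligned", call. = FALSE)
  den <- if (denominator == "b") field_b else field_a
  masked <- abs(den) < mask_eps
  if (all(masked))
    stop("all nodes masked: denominator field is identically ~0", call. = FALSE)
  pct <- rep(NA_real_, length(den))
  pct[!masked] <- 100 * (field_a[!masked] - field_b[!masked]) / den[!masked]
  live <- pct[!masked]
  summ <- c(beyond_5 = mean(abs(live) > 5),
            beyond_10 = mean(abs(live) > 10),
            beyond_20 = mean(abs(live) > 20))
  structure(list(percent = pct, masked = masked, summary = summ),
            class = "percent_diff_map")
}

#' @export
print.percent_diff_map <- function(x, ...) {
  n <- length(x$percent)
  cat(sprintf("<percent_diff_map> %d nodes (%d masked)\n", n, sum(x$masked)))
  cat(sprintf("  |change| > 5%%: %.1f%%   > 10%%: %.1f%%   > 20%%: %.1f%%\n",
              100 * x$summary[1], 100 * x$summary[2], 100 * x$summary[3]))
  invisible(x)
}
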