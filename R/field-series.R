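#' Time-resolved vector field on a point set
#'
#' The substrate every post-processing stage works on: a cloud of points with
#' a 3-vector per point per time step. `kind` distinguishes interior velocity
#' fields (m/s) from surface wall-shear fields (Pa); surface fields must
#' carry unit surface normals.
#'
#' @param points n x 3 matrix of point coordinates, m.
#' @param times strictly increasing sample times, s.
#' @param vectors numeric array of dim `(n_times, n_points, 3)`.
#' @param kind `"velocity"` or `"wall_shear"`.
#' @param normals n x 3 matrix of unit surface normals (required for
#'   `wall_shear`).
#' @param period cycle period, s (`NA` if not periodic).
#' @return an object of class `field_series`.
#' @export
field_series <- function(points, times, vectors,
                         kind = c("velocity", "wall_shear"),
                         normals = NULL, period = NA_real_) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be n x 3", call. = FALSE)
  points <- matrix(as.numeric(points), nrow(points), 3)  # strip attributes
  times <- as.numeric(times)
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!is.array(vectors) || length(dim(vectors)) != 3)
    stop("`vectors` must be an (n_times, n_points, 3) array", call. = FALSE)
  d <- dim(vectors)
  if (d[1] != length(times) || d[2] != nrow(points) || d[3] != 3)
    stop(sprintf("vector array dim (%d,%d,%d) does not match %d times x %d points x 3",
                 d[1], d[2], d[3], length(times), nrow(points)), call. = FALSE)
  if (kind == "wall_shear") {
    if (is.null(normals))
      stop("wall_shear fields require surface `normals`", call. = FALSE)
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points)))
      stop("`normals` must match `points` in shape", call. = FALSE)
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("`normals` must be unit length", call. = FALSE)
  }
  structure(list(points = points, times = times, vectors = vectors,
                 kind = kind, normals = normals, period = period),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> kind = %s: %d points, %d time steps over [%g, %g] s\n",
              x$kind, nrow(x$points), length(x$times),
              x$times[1], x$times[length(x$times)]))
  if (!is.na(x$period)) cat(sprintf("  cycle period: %g s\n", x$period))
  invisible(x)
}

#' @export
`[.field_series` <- function(x, i, ...) {
  # subset by time index, keeping the full point set
  field_series(x$points, x$times[i], x$vectors[i, , , drop = FALSE],
               kind = x$kind, normals = x$normals, period = x$period)
}

# n_points x 3 matrix of vectors at one time index
field_at <- function(field, time_index) {
  v <- field$vectors[time_index, , , drop = FALSE]
  dim(v) <- dim(field$vectors)[2:3]
  v
}

# per-time per-point vector magnitudes: (n_times x n_points) matrix
field_magnitudes <- function(field) {
  sqrt(apply(field$vectors^2, c(1, 2), sum))
}
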