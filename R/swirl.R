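#' Velocity-gradient tensor on a point cloud
#'
#' Estimates the per-point velocity-gradient tensor
#' \eqn{J_{ab} = \partial v_a / \partial x_b} of a volume velocity field at
#' one time step.
#'
#' Two estimators are available. `"structured"` applies second-order central
#' differences (one-sided at boundaries) and requires the points to be a
#' [cartesian_lattice()] (or any field carrying `lattice` metadata).
#' `"knn_lsq"` works on arbitrary point clouds: each point's tensor is the
#' linear part of a least-squares fit \eqn{v(x) \approx v_0 + J (x - x_0)}
#' over its `k` nearest neighbours; it is exact for affine fields.
#'
#' @param field a velocity [field_series()].
#' @param time_index which time step to differentiate (default 1).
#' @param method `"structured"` or `"knn_lsq"`.
#' @param k neighbour count for `"knn_lsq"` (>= 4; neighbourhoods must be
#'   non-coplanar).
#' @return numeric array of dim `(n_points, 3, 3)`.
#' @export
velocity_gradient <- function(field, time_index = 1,
                              method = c("knn_lsq", "structured"), k = 12) {
  stopifnot(inherits(field, "field_series"))
  method <- match.arg(method)
  v <- field_at(field, time_index)
  pts <- field$points
  if (method == "structured") {
    lat <- field$lattice
    if (is.null(lat) || is.null(lat$dims))
      lat <- list(dims = attr(pts, "dims"), spacing = attr(pts, "spacing"))
    if (is.null(lat$dims))
      stop("structured gradients need lattice metadata (see cartesian_lattice)",
           call. = FALSE)
    return(structured_gradient(v, lat$dims, lat$spacing))
  }
  knn_lsq_gradient(pts, v, k)
}

# central differences on an x-fastest lattice; one-sided at the faces
structured_gradient <- function(v, dims, spacing) {
  n <- nrow(v)
  stopifnot(prod(dims) == n)
  J <- array(NA_real_, dim = c(n, 3, 3))
  for (a in 1:3) {
    comp <- array(v[, a], dim = dims)
    for (b in 1:3) {
      d <- dims[b]
      h <- spacing[b]
      der <- array(NA_real_, dim = dims)
      idx_all <- seq_len(d)
      take <- function(i) {
        idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
        idx[[b]] <- i
        do.call(`[`, c(list(comp), idx, list(drop = FALSE)))
      }
      assign_slice <- function(arr, i, val) {
        idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
        idx[[b]] <- i
        do.call(`[<-`, c(list(arr), idx, list(value = val)))
      }
      interior <- idx_all[-c(1, d)]
      der <- assign_slice(der, interior,
                          (take(interior + 1) - take(interior - 1)) / (2 * h))
      der <- assign_slice(der, 1, (take(2) - take(1)) / h)
      der <- assign_slice(der, d, (take(d) - take(d - 1)) / h)
      J[, a, b] <- as.vector(der)
    }
  }
  J
}

knn_lsq_gradient <- function(pts, v, k) {
  n <- nrow(pts)
  if (k < 4) stop("knn_lsq needs k >= 4 neighbours", call. = FALSE)
  if (n < k + 1) stop("fewer points than k + 1", call. = FALSE)
  D2 <- as.matrix(stats::dist(pts))^2
  J <- array(NA_real_, dim = c(n, 3, 3))
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    kk <- k
    repeat {
      nb <- ord[seq_len(min(kk + 1, n))]   # includes the point itself
      X <- cbind(1, sweep(pts[nb, , drop = FALSE], 2, pts[i, ]))
      qrX <- qr(X)
      if (qrX$rank == 4) break
      # distance ties / locally flat shells: widen the neighbourhood before
      # declaring the cloud degenerate
      if (kk + 1 >= n)
        stop(sprintf("degenerate (coplanar) neighbourhood at point %d", i),
             call. = FALSE)
      kk <- min(2 * kk, n - 1)
    }
    beta <- qr.coef(qrX, v[nb, , drop = FALSE])
    J[i, , ] <- t(beta[2:4, ])
  }
  J
}

#' Swirling strength of a velocity-gradient tensor
#'
#' The swirling strength \eqn{\lambda_{ci}} is the imaginary part of the
#' complex-conjugate eigenvalue pair of the velocity-gradient tensor — a
#' frame-independent measure of the local fluid rotation rate; zero when the
#' spectrum is entirely real (pure strain/shear). Eigenvalues are taken from
#' the closed-form characteristic cubic (Cardano), with a fallback to a
#' general eigensolver when the cubic discriminant is within roundoff of the
#' real/complex boundary.
#'
#' @param J a 3 x 3 matrix, or an array of dim `(n, 3, 3)` of tensors (1/s).
#' @return swirling strength(s), >= 0, in 1/s.
#' @examples
#' J <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 0), 3, 3)  # rotation at 2 rad/s
#' swirling_strength(J)
#' @export
swirling_strength <- function(J) {
  if (is.matrix(J)) {
    stopifnot(all(dim(J) == c(3, 3)))
    return(ss_one(J))
  }
  stopifnot(is.array(J), length(dim(J)) == 3, all(dim(J)[2:3] == c(3, 3)))
  apply(J, 1, function(m) ss_one(matrix(m, 3, 3)))
}

ss_one <- function(J) {
  if (any(!is.finite(J))) stop("non-finite tensor entries", call. = FALSE)
  scale <- max(abs(J))
  if (scale == 0) return(0)
  A <- J / scale
  i1 <- A[1, 1] + A[2, 2] + A[3, 3]
  i2 <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1] +
        A[1, 1] * A[3, 3] - A[1, 3] * A[3, 1] +
        A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]
  i3 <- det(A)
  # depressed cubic x^3 + p x + q, lambda = x + i1/3
  p <- i2 - i1^2 / 3
  q <- -2 * i1^3 / 27 + i1 * i2 / 3 - i3
  disc <- (q / 2)^2 + (p / 3)^3   # > 0: one real + complex pair
  if (abs(disc) < 1e-12) {
    ev <- eigen(A, only.values = TRUE)$values
    return(scale * max(abs(Im(ev))))
  }
  if (disc < 0) return(0)          # three distinct real roots
  sq <- sqrt(disc)
  u <- -q / 2 + sq
  v <- -q / 2 - sq
  s <- if (abs(u) >= abs(v)) sign(u) * abs(u)^(1 / 3) else {
    # derive from the larger-magnitude branch to dodge cancellation
    sv <- sign(v) * abs(v)^(1 / 3)
    if (sv == 0) 0 else -p / (3 * sv)
  }
  x1 <- if (s == 0) 0 else s - p / (3 * s)   # the real root
  quad_disc <- x1^2 - 4 * (p + x1^2)         # of x^2 + x1 x + (p + x1^2)
  if (quad_disc >= 0) return(0)
  scale * sqrt(-quad_disc) / 2
}

#' Cross-sectional sampling planes along a centerline
#'
#' Places `n` planes equally spaced by arclength along an ordered centerline
#' polyline, each with its normal along the local tangent. Points within
#' `slab_halfwidth` of a plane (along its normal) are the plane's sample set.
#'
#' @param centerline m x 3 matrix of ordered centerline points (m >= 2).
#' @param n number of planes (default 38, dense enough that plane statistics
#'   approximate a continuous profile along the vessel).
#' @param slab_halfwidth half-thickness of the sampling slab, m; default is
#'   half the mean plane spacing.
#' @return object of class `plane_set`: list with `origin` (n x 3), `normal`
#'   (n x 3, unit), `arclength` (n), `slab_halfwidth`.
#' @export
make_planes <- function(centerline, n = 38, slab_halfwidth = NULL) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2)
    stop("centerline needs at least 2 points", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  seg <- diff(centerline)
  seg_len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(seg_len))
  L <- s[length(s)]
  targets <- if (n == 1) L / 2 else seq(0, L, length.out = n)
  origin <- sapply(1:3, function(a)
    stats::approx(s, centerline[, a], xout = targets)$y)
  origin <- matrix(origin, ncol = 3)
  # tangent of the segment each target falls in
  idx <- pmin(findInterval(targets, s, rightmost.closed = TRUE),
              nrow(seg))
  normal <- seg[idx, , drop = FALSE] / seg_len[idx]
  if (is.null(slab_halfwidth))
    slab_halfwidth <- if (n > 1) 0.5 * L / (n - 1) else L / 4
  structure(list(origin = origin, normal = normal, arclength = targets,
                 slab_halfwidth = slab_halfwidth),
            class = "plane_set")
}

#' @export
print.plane_set <- function(x, ...) {
  cat(sprintf("<plane_set> %d planes over %.4g m of centerline (slab halfwidth %.3g m)\n",
              nrow(x$origin), max(x$arclength), x$slab_halfwidth))
  invisible(x)
}

#' Mean swirling strength over one sampling plane
#'
#' Arithmetic mean of point-wise swirling strength over the field points
#' lying within the plane's slab. Returns `NA` (with a warning) when no
#' point falls inside the slab.
#'
#' @param field a velocity [field_series()].
#' @param plane_origin,plane_normal plane origin and unit normal.
#' @param slab_halfwidth slab half-thickness, m.
#' @param time_index time step to evaluate.
#' @param ss optional precomputed per-point swirling strengths (skips the
#'   gradient computation).
#' @param method,k passed to [velocity_gradient()].
#' @return mean swirling strength, 1/s.
#' @export
plane_mean_ss <- function(field, plane_origin, plane_normal, slab_halfwidth,
                          time_index = 1, ss = NULL,
                          method = c("knn_lsq", "structured"), k = 12) {
  method <- match.arg(method)
  d <- as.vector((sweep(field$points, 2, plane_origin)) %*% plane_normal)
  inside <- abs(d) <= slab_halfwidth
  if (!any(inside)) {
    warning("no field points inside plane slab; value marked missing",
            call. = FALSE)
    return(NA_real_)
  }
  if (is.null(ss)) {
    J <- velocity_gradient(field, time_index, method = method, k = k)
    ss <- swirling_strength(J)
  }
  mean(ss[inside])
}

#' Plane-wise swirling-strength profile over a cycle
#'
#' Computes the per-plane, per-time mean swirling strength of a volume
#' velocity field, the per-plane time average (TASS), and the normalised
#' mean SS across planes — the package's reduced description of how much
#' rotational flow each vessel cross-section carries and how it evolves
#' through the cardiac cycle.
#'
#' @param field a velocity [field_series()] spanning one cycle.
#' @param planes a [make_planes()] plane set.
#' @param method,k gradient estimator options, see [velocity_gradient()].
#' @param period cycle period, s (defaults to the field's).
#' @return object of class `swirl_profile`: `ss` (n_planes x n_times
#'   matrix), `times`, `tass` (per plane), `mean_ss` (per time, mean over
#'   planes), `normalised_mean_ss` (per time, peak scaled to 1).
#' @export
swirl_profile <- function(field, planes, method = c("knn_lsq", "structured"),
                          k = 12, period = NULL) {
  stopifnot(inherits(field, "field_series"), inherits(planes, "plane_set"))
  method <- match.arg(method)
  n_planes <- nrow(planes$origin)
  n_times <- length(field$times)
  ssm <- matrix(NA_real_, n_planes, n_times)
  for (j in seq_len(n_times)) {
    J <- velocity_gradient(field, j, method = method, k = k)
    ss_pts <- swirling_strength(J)
    for (i in seq_len(n_planes)) {
      ssm[i, j] <- suppressWarnings(
        plane_mean_ss(field, planes$origin[i, ], planes$normal[i, ],
                      planes$slab_halfwidth, time_index = j, ss = ss_pts))
    }
  }
  if (is.null(period)) period <- field$period
  structure(list(ss = ssm, times = field$times,
                 tass = tass(ssm, field$times, period),
                 mean_ss = colMeans(ssm, na.rm = TRUE),
                 normalised_mean_ss = normalised_mean_ss(ssm)),
            class = "swirl_profile")
}

#' @export
print.swirl_profile <- function(x, ...) {
  cat(sprintf("<swirl_profile> %d planes x %d time steps\n",
              nrow(x$ss), ncol(x$ss)))
  cat(sprintf("  TASS range: [%.4g, %.4g] 1/s\n",
              min(x$tass, na.rm = TRUE), max(x$tass, na.rm = TRUE)))
  invisible(x)
}

#' Time-averaged swirling strength per plane
#'
#' Trapezoidal time average \eqn{(1/T)\int_0^T SS\,dt} of each plane's mean
#' swirling strength over one cycle.
#'
#' @param ss numeric vector (one plane) or n_planes x n_times matrix.
#' @param times sample times, s.
#' @param period cycle period, s; defaults to the span of `times`.
#' @return per-plane TASS, 1/s.
#' @export
tass <- function(ss, times, period = NULL) {
  if (is.null(period) || is.na(period))
    period <- times[length(times)] - times[1]
  if (is.matrix(ss)) return(apply(ss, 1, tass, times = times, period = period))
  if (anyNA(ss)) return(NA_real_)
  trapz(times, ss) / period
}

#' Normalised mean swirling strength across planes
#'
#' Unweighted arithmetic mean of the per-plane SS at each time (planes with
#' missing values excluded), rescaled by its own cycle maximum so the result
#' lies in [0, 1] and attains 1 — a shape descriptor of global rotational
#' activity that is comparable across cases regardless of absolute
#' magnitude. The unnormalised mean is available as the `mean_ss` component
#' of [swirl_profile()].
#'
#' @param ss n_planes x n_times matrix of plane-mean swirling strengths.
#' @return numeric vector over time in [0, 1].
#' @export
normalised_mean_ss <- function(ss) {
  if (!is.matrix(ss)) ss <- matrix(ss, nrow = 1)
  m <- colMeans(ss, na.rm = TRUE)
  peak <- max(m)
  if (!is.finite(peak) || peak <= 0)
    stop("mean swirling strength is identically zero: nothing to normalise",
         call. = FALSE)
  m / peak
}
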