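#' Specification of an analytic Womersley pulsatile pipe flow
#'
#' Defines the exact laminar solution for pressure-gradient-driven flow in a
#' rigid circular pipe: a steady Poiseuille component plus any number of
#' oscillatory harmonics. Amplitudes are amplitudes of the driving gradient
#' \eqn{-dp/dz} (Pa/m) — the same sign convention as `steady_gradient`, so a
#' positive-amplitude harmonic at phase 0 pushes flow in +z in the
#' low-frequency limit. Each harmonic k with angular frequency
#' \eqn{\omega_k}, amplitude \eqn{A_k} and phase \eqn{\phi_k} contributes
#' \deqn{u_k(r,t) = \mathrm{Re}\left\{\frac{-i A_k}{\rho \omega_k}
#'   \left(1 - \frac{J_0(i^{3/2}\alpha_k r/R)}{J_0(i^{3/2}\alpha_k)}\right)
#'   e^{i(\omega_k t + \phi_k)}\right\}}
#' with Womersley number \eqn{\alpha_k = R\sqrt{\omega_k \rho / \mu}}.
#' Because these fields have closed-form wall shear, they serve as ground
#' truth for the wall-shear-index pipeline.
#'
#' @param radius pipe radius, m.
#' @param viscosity dynamic viscosity, Pa s.
#' @param density fluid density, kg/m^3 (default the package's blood value).
#' @param steady_gradient steady driving pressure gradient \eqn{-dp/dz},
#'   Pa/m (positive drives flow in +z).
#' @param harmonics data frame with columns `omega` (rad/s), `amplitude`
#'   (Pa/m) and `phase` (rad); zero rows for pure Poiseuille flow.
#' @param period cycle period, s; defaults to \eqn{2\pi/\min\omega} (1 s for
#'   a steady spec). All harmonics must complete whole cycles in the period.
#' @param n_radial,n_theta,n_axial lattice resolution of the generated
#'   volume field (radial shells, azimuthal stations, axial stations).
#' @param n_steps time steps per cycle (the grid carries both endpoints, so
#'   the series is exactly periodic sample-for-sample).
#' @param pipe_length axial extent of the lattice, m.
#' @param seed integer seed recorded in the generated fields' metadata.
#' @return an object of class `womersley_spec`.
#' @seealso [womersley_pipe()] to realise the fields.
#' @export
womersley_spec <- function(radius = 0.01, viscosity = 0.0035, density = 1056,
                           steady_gradient = 0,
                           harmonics = data.frame(omega = numeric(),
                                                  amplitude = numeric(),
                                                  phase = numeric()),
                           period = NULL, n_radial = 8, n_theta = 8,
                           n_axial = 3, n_steps = 40, pipe_length = NULL,
                           seed = 1L) {
  stopifnot(radius > 0, viscosity > 0, density > 0,
            n_radial >= 2, n_theta >= 3, n_axial >= 2, n_steps >= 2)
  harmonics <- as.data.frame(harmonics)
  if (nrow(harmonics) &&
      !all(c("omega", "amplitude", "phase") %in% names(harmonics)))
    stop("`harmonics` needs columns omega, amplitude, phase", call. = FALSE)
  if (any(harmonics$omega <= 0))
    stop("harmonic frequencies must be positive", call. = FALSE)
  alpha <- radius * sqrt(harmonics$omega * density / viscosity)
  if (any(alpha > 50))
    stop(sprintf("Womersley number %.1f exceeds the supported cap of 50",
                 max(alpha)), call. = FALSE)
  if (is.null(period))
    period <- if (nrow(harmonics)) 2 * pi / min(harmonics$omega) else 1
  cycles <- harmonics$omega * period / (2 * pi)
  if (any(abs(cycles - round(cycles)) > 1e-9))
    stop("every harmonic must complete an integer number of cycles per period",
         call. = FALSE)
  if (is.null(pipe_length)) pipe_length <- 4 * radius
  structure(list(radius = radius, viscosity = viscosity, density = density,
                 steady_gradient = steady_gradient, harmonics = harmonics,
                 alpha = alpha, period = period, n_radial = n_radial,
                 n_theta = n_theta, n_axial = n_axial, n_steps = n_steps,
                 pipe_length = pipe_length, seed = as.integer(seed)),
            class = "womersley_spec")
}

#' Analytic Womersley velocity and wall shear
#'
#' Closed-form evaluators backing [womersley_pipe()]: axial velocity
#' \eqn{u(r,t)} and the axial wall-shear component
#' \eqn{\tau_w(t) = -\mu\,\partial u/\partial r |_{r=R}} (positive when the
#' near-wall fluid drags the wall in +z).
#'
#' @param r radial position(s), m, in `[0, radius]`.
#' @param t time(s), s.
#' @param spec a [womersley_spec()].
#' @return `womersley_velocity`: matrix `length(r)` x `length(t)` of axial
#'   velocity (m/s); `womersley_wall_shear`: vector along `t` of axial wall
#'   shear (Pa).
#' @export
womersley_velocity <- function(r, t, spec) {
  stopifnot(inherits(spec, "womersley_spec"))
  R <- spec$radius
  u <- outer(spec$steady_gradient * (R^2 - r^2) / (4 * spec$viscosity),
             rep(1, length(t)))
  if (nrow(spec$harmonics)) {
    i32 <- complex(modulus = 1, argument = 3 * pi / 4)   # i^{3/2}
    for (k in seq_len(nrow(spec$harmonics))) {
      om <- spec$harmonics$omega[k]
      A <- spec$harmonics$amplitude[k]
      ph <- spec$harmonics$phase[k]
      za <- i32 * spec$alpha[k]
      prof <- (-1i * A / (spec$density * om)) *
        (1 - besselJ0_complex(za * r / R) / besselJ0_complex(za))
      u <- u + Re(outer(prof, exp(1i * (om * t + ph))))
    }
  }
  u
}

#' @rdname womersley_velocity
#' @export
womersley_wall_shear <- function(t, spec) {
  stopifnot(inherits(spec, "womersley_spec"))
  R <- spec$radius
  mu <- spec$viscosity
  # steady part: du/dr|_R = -G R / (2 mu)  ->  tau = +G R / 2
  tau <- rep(spec$steady_gradient * R / 2, length(t))
  if (nrow(spec$harmonics)) {
    i32 <- complex(modulus = 1, argument = 3 * pi / 4)
    for (k in seq_len(nrow(spec$harmonics))) {
      om <- spec$harmonics$omega[k]
      A <- spec$harmonics$amplitude[k]
      ph <- spec$harmonics$phase[k]
      za <- i32 * spec$alpha[k]
      dudr_amp <- (-1i * A / (spec$density * om)) *
        (za / R) * besselJ1_complex(za) / besselJ0_complex(za)
      tau <- tau - mu * Re(dudr_amp * exp(1i * (om * t + ph)))
    }
  }
  tau
}

# structured cylindrical lattice: one axis point per z plus n_theta points on
# each positive radial shell
cylinder_lattice <- function(R, n_radial, n_theta, zs) {
  radii <- seq(0, R, length.out = n_radial)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  pts <- do.call(rbind, lapply(zs, function(z) {
    shell <- do.call(rbind, lapply(radii[-1], function(rr)
      cbind(rr * cos(theta), rr * sin(theta), z)))
    rbind(c(0, 0, z), shell)
  }))
  attr(pts, "radius") <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  pts
}

#' Generate Womersley volume and wall fields
#'
#' Realises a [womersley_spec()] on a structured cylindrical lattice over one
#' cycle: a volume velocity field (axial flow \eqn{u(r,t)\hat z}) and a wall
#' field carrying the wall-shear vector \eqn{\tau_w(t)\hat z} with inward
#' surface normals. Both series include the cycle endpoint, so they are
#' exactly periodic.
#'
#' @param spec a [womersley_spec()].
#' @return list with elements `volume` and `wall`, both [field_series()].
#' @examples
#' ws <- womersley_spec(steady_gradient = 100)
#' f <- womersley_pipe(ws)
#' max(field_magnitudes(f$wall))    # = G R / 2
#' @export
womersley_pipe <- function(spec) {
  stopifnot(inherits(spec, "womersley_spec"))
  R <- spec$radius
  times <- seq(0, spec$period, length.out = spec$n_steps + 1)
  zs <- seq(0, spec$pipe_length, length.out = spec$n_axial)

  pts <- cylinder_lattice(R, spec$n_radial, spec$n_theta, zs)
  rr <- attr(pts, "radius")
  uu <- womersley_velocity(rr, times, spec)   # n_points x n_times
  vol_vec <- array(0, dim = c(length(times), nrow(pts), 3))
  vol_vec[, , 3] <- t(uu)
  volume <- field_series(pts, times, vol_vec, kind = "velocity",
                         period = spec$period)

  theta <- seq(0, 2 * pi, length.out = spec$n_theta + 1)[-(spec$n_theta + 1)]
  wpts <- do.call(rbind, lapply(zs, function(z)
    cbind(R * cos(theta), R * sin(theta), z)))
  wnorm <- cbind(-wpts[, 1] / R, -wpts[, 2] / R, 0)
  tau <- womersley_wall_shear(times, spec)
  wall_vec <- array(0, dim = c(length(times), nrow(wpts), 3))
  wall_vec[, , 3] <- matrix(tau, length(times), nrow(wpts))
  wall <- field_series(wpts, times, wall_vec, kind = "wall_shear",
                       normals = wnorm, period = spec$period)

  list(volume = volume, wall = wall, seed = spec$seed)
}

#' Regular Cartesian point lattice
#'
#' Convenience generator for structured volume point sets. The returned
#' matrix carries `dims` and `spacing` attributes so that
#' [velocity_gradient()] can use central differences on it.
#'
#' @param n integer 3-vector of points per axis.
#' @param spacing grid spacing, m (scalar or 3-vector).
#' @param origin coordinates of the lattice corner.
#' @return `prod(n)` x 3 matrix of coordinates (x fastest), with attributes
#'   `dims` and `spacing`.
#' @export
cartesian_lattice <- function(n = c(7, 7, 7), spacing = 1e-3,
                              origin = c(0, 0, 0)) {
  n <- as.integer(n)
  stopifnot(length(n) == 3, all(n >= 2))
  spacing <- rep(spacing, length.out = 3)
  g <- expand.grid(x = (seq_len(n[1]) - 1) * spacing[1] + origin[1],
                   y = (seq_len(n[2]) - 1) * spacing[2] + origin[2],
                   z = (seq_len(n[3]) - 1) * spacing[3] + origin[3])
  pts <- as.matrix(g)
  dimnames(pts) <- NULL
  attr(pts, "dims") <- n
  attr(pts, "spacing") <- spacing
  pts
}

#' Rigid-body vortex velocity field
#'
#' Solid-body rotation \eqn{v(x) = \omega\, \hat a \times x} about an axis
#' through the origin, constant in time. Its velocity-gradient tensor has the
#' complex eigenpair \eqn{\pm i\omega}, making it exact ground truth for
#' swirling-strength recovery.
#'
#' @param omega rotation rate, rad/s.
#' @param axis rotation axis (unit 3-vector).
#' @param points n x 3 coordinates, m.
#' @param times sample times, s.
#' @return a velocity [field_series()].
#' @export
rigid_vortex_field <- function(omega, axis = c(0, 0, 1), points,
                               times = 0) {
  axis <- as.numeric(axis)
  len <- sqrt(sum(axis^2))
  if (!is.finite(len) || len < 1e-12)
    stop("`axis` must be a nonzero vector", call. = FALSE)
  if (abs(len - 1) > 1e-8)
    stop("`axis` must be unit length", call. = FALSE)
  points <- as.matrix(points)
  v <- omega * cbind(axis[2] * points[, 3] - axis[3] * points[, 2],
                     axis[3] * points[, 1] - axis[1] * points[, 3],
                     axis[1] * points[, 2] - axis[2] * points[, 1])
  vec <- array(0, dim = c(length(times), nrow(points), 3))
  for (i in seq_along(times)) vec[i, , ] <- v
  fs <- field_series(points, times, vec, kind = "velocity")
  # preserve lattice structure if the caller passed a cartesian_lattice
  fs$lattice <- list(dims = attr(points, "dims"),
                     spacing = attr(points, "spacing"))
  fs
}

#' Mass-conserving branching-network outlet flows
#'
#' Splits an inlet flow waveform across named outlets by fixed fractions,
#' \eqn{Q_i(t) = s_i\,Q_{in}(t)}, emulating the outlet flow series of a
#' multi-branch arterial model. Fractions may sum to less than one; the
#' remainder (wall-motion / leakage allowance) is recorded, never silently
#' renormalised.
#'
#' @param inlet inlet flow [hemo_series()].
#' @param splits named nonnegative fractions summing to at most 1.
#' @param noise_sd relative Gaussian noise per outlet sample (0 = exact).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return named list of outlet [hemo_series()] with attributes `splits`,
#'   `residual_fraction` and `seed`.
#' @export
branching_network_flows <- function(inlet, splits, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(inlet, "hemo_series"))
  splits <- unlist(splits)
  if (is.null(names(splits)) || any(!nzchar(names(splits))))
    stop("`splits` must be a named vector of outlet fractions", call. = FALSE)
  if (any(splits < 0)) stop("splits must be nonnegative", call. = FALSE)
  if (sum(splits) > 1 + 1e-12)
    stop(sprintf("splits sum to %.4f > 1", sum(splits)), call. = FALSE)
  if (noise_sd > 0) set.seed(as.integer(seed))
  out <- lapply(seq_along(splits), function(i) {
    v <- splits[i] * inlet$value
    if (noise_sd > 0)
      v <- v * (1 + stats::rnorm(length(v), 0, noise_sd))
    hemo_series(inlet$time_s, v, unit = series_unit(inlet),
                period = series_period(inlet))
  })
  names(out) <- names(splits)
  attr(out, "splits") <- splits
  attr(out, "residual_fraction") <- 1 - sum(splits)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Add reproducible Gaussian noise to a series or field
#'
#' Multiplicative perturbation `x * (1 + sigma * eps)` with standard normal
#' `eps`, so the sample coefficient of variation of a constant signal
#' approaches `sigma`. `sigma = 0` returns the input unchanged; the same seed
#' always reproduces the same perturbation.
#'
#' @param x a [hemo_series()] or [field_series()].
#' @param sigma relative noise level (>= 0).
#' @param seed integer RNG seed.
#' @return same type as `x`.
#' @export
add_noise <- function(x, sigma, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) return(x)
  UseMethod("add_noise")
}

#' @export
add_noise.hemo_series <- function(x, sigma, seed = 1L) {
  set.seed(as.integer(seed))
  hemo_series(x$time_s, x$value * (1 + stats::rnorm(nrow(x), 0, sigma)),
              unit = series_unit(x), period = series_period(x))
}

#' @export
add_noise.field_series <- function(x, sigma, seed = 1L) {
  set.seed(as.integer(seed))
  eps <- array(stats::rnorm(length(x$vectors), 0, sigma), dim = dim(x$vectors))
  out <- x
  out$vectors <- x$vectors * (1 + eps)
  out
}
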