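# shared fixtures and independent oracles for the suite

patient_timing <- function() cardiac_timing()   # 0.731 / 0.273 / 0.961

# single-node wall-shear series alternating +tau/-tau along x with equal
# dwell; sign(sin) puts a zero sample at each switch so the trapezoidal
# time-mean vector is exactly zero
alternating_wall_series <- function(tau = 2, period = 0.731, n = 41) {
  times <- seq(0, period, length.out = n)
  vec <- array(0, dim = c(n, 1, 3))
  s <- sin(2 * pi * times / period)
  vec[, 1, 1] <- tau * sign(s) * (abs(s) > 1e-9)
  field_series(matrix(0, 1, 3), times, vec, kind = "wall_shear",
               normals = matrix(c(0, 0, 1), 1, 3), period = period)
}

steady_wall_series <- function(tau = 2, period = 0.731, n = 21) {
  times <- seq(0, period, length.out = n)
  vec <- array(0, dim = c(n, 1, 3))
  vec[, 1, 1] <- tau
  field_series(matrix(0, 1, 3), times, vec, kind = "wall_shear",
               normals = matrix(c(0, 0, 1), 1, 3), period = period)
}

# random wall-shear field series on n_pts nodes
random_wall_series <- function(n_pts = 10, n_t = 30, period = 0.731,
                               seed = 1) {
  set.seed(seed)
  times <- seq(0, period, length.out = n_t)
  vec <- array(stats::rnorm(n_t * n_pts * 3), dim = c(n_t, n_pts, 3))
  vec[n_t, , ] <- vec[1, , ]   # periodic endpoint
  nrm <- matrix(stats::rnorm(n_pts * 3), n_pts, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  field_series(matrix(stats::rnorm(n_pts * 3), n_pts, 3), times, vec,
               kind = "wall_shear", normals = nrm, period = period)
}

# independent composite-trapezoid oracle (deliberately re-derived here)
oracle_trapz <- function(t, y) {
  n <- length(t)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + (y[i] + y[i + 1]) * (t[i + 1] - t[i]) / 2
  s
}

# brute-force swirling strength: roots of the characteristic cubic via
# polyroot, completely independent of the closed-form path
oracle_swirl <- function(J) {
  i1 <- sum(diag(J))
  i2 <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1] +
        J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1] +
        J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2]
  i3 <- det(J)
  roots <- polyroot(c(-i3, i2, -i1, 1))
  max(abs(Im(roots)))
}

# principal-stress route to the Von Mises measure
oracle_von_mises <- function(s) {
  p <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  sqrt(0.5 * ((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2))
}

random_orthogonal <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}
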