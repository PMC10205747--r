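linear_field <- function(A, pts, b = c(0, 0, 0)) {
  v <- t(A %*% t(pts)) + matrix(b, nrow(pts), 3, byrow = TRUE)
  vec <- array(0, dim = c(1, nrow(pts), 3))
  vec[1, , ] <- v
  fs <- field_series(pts, 0, vec, kind = "velocity")
  fs$lattice <- list(dims = attr(pts, "dims"), spacing = attr(pts, "spacing"))
  fs
}

test_that("gradient estimators are exact on affine fields", {
  set.seed(21)
  pts <- cartesian_lattice(c(5, 6, 4), c(1e-3, 2e-3, 1.5e-3))
  for (trial in 1:3) {
    A <- matrix(stats::rnorm(9), 3, 3)
    f <- linear_field(A, pts, b = stats::rnorm(3))
    Js <- velocity_gradient(f, method = "structured")
    Jk <- velocity_gradient(f, method = "knn_lsq", k = 10)
    for (i in c(1, 17, nrow(pts))) {
      expect_equal(matrix(Js[i, , ], 3, 3), A, tolerance = 1e-9)
      expect_equal(matrix(Jk[i, , ], 3, 3), A, tolerance = 1e-9)
    }
  }
  # uniform field: zero tensor; constant offset never changes the gradient
  f0 <- linear_field(matrix(0, 3, 3), pts, b = c(3, -1, 2))
  expect_true(all(abs(velocity_gradient(f0, method = "knn_lsq")) < 1e-12))
})

test_that("structured gradient converges at second order on smooth fields", {
  fld <- function(p) cbind(sin(p[, 1]) * cos(p[, 2]),
                           p[, 2]^2 * p[, 3],
                           exp(p[, 1] / 2) + p[, 3]^2)
  jac <- function(p) {   # analytic Jacobian at one point
    rbind(c(cos(p[1]) * cos(p[2]), -sin(p[1]) * sin(p[2]), 0),
          c(0, 2 * p[2] * p[3], p[2]^2),
          c(exp(p[1] / 2) / 2, 0, 2 * p[3]))
  }
  err_at <- function(h) {
    pts <- cartesian_lattice(c(7, 7, 7), h, origin = c(0.3, 0.2, 0.1))
    vec <- array(0, dim = c(1, nrow(pts), 3)); vec[1, , ] <- fld(pts)
    f <- field_series(pts, 0, vec, kind = "velocity")
    f$lattice <- list(dims = attr(pts, "dims"), spacing = attr(pts, "spacing"))
    J <- velocity_gradient(f, method = "structured")
    i <- 172   # interior point
    max(abs(matrix(J[i, , ], 3, 3) - jac(pts[i, ])))
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_gt(e1 / e2, 3.4)   # ~4 for O(h^2)
})

test_that("coplanar neighbourhoods are reported as rank deficient", {
  pts <- cbind(stats::runif(12), stats::runif(12), 0)   # flat in z
  vec <- array(stats::rnorm(12 * 3), dim = c(1, 12, 3))
  f <- field_series(pts, 0, vec, kind = "velocity")
  expect_error(velocity_gradient(f, method = "knn_lsq", k = 8),
               "coplanar|degenerate")
})

test_that("swirling strength matches eigenstructure on canonical tensors", {
  rot <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(swirling_strength(rot), 2)
  sym <- matrix(c(1, 2, 3, 2, -1, 0.5, 3, 0.5, 2), 3, 3)
  expect_equal(swirling_strength(sym), 0)
  expect_equal(swirling_strength(matrix(0, 3, 3)), 0)
  expect_error(swirling_strength(matrix(NaN, 3, 3)), "non-finite")
})

test_that("swirling strength agrees with a brute-force cubic-root oracle", {
  set.seed(33)
  worst <- 0
  for (i in 1:1000) {
    J <- matrix(stats::rnorm(9, sd = sample(c(0.1, 1, 50), 1)), 3, 3)
    d <- abs(swirling_strength(J) - oracle_swirl(J)) / max(norm(J, "F"), 1)
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-9)
})

test_that("swirling strength is invariant under orthogonal conjugation", {
  set.seed(8)
  for (i in 1:50) {
    J <- matrix(stats::rnorm(9), 3, 3)
    Q <- random_orthogonal(i)
    expect_equal(swirling_strength(Q %*% J %*% t(Q)), swirling_strength(J),
                 tolerance = 1e-9)
  }
})

test_that("zero swirl coincides with an all-real characteristic spectrum", {
  set.seed(55)
  for (i in 1:200) {
    J <- matrix(stats::rnorm(9), 3, 3)
    roots <- polyroot(c(-det(J),
                        J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1] +
                          J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1] +
                          J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2],
                        -sum(diag(J)), 1))
    all_real <- max(abs(Im(roots))) < 1e-8
    expect_identical(swirling_strength(J) < 1e-8, all_real)
  }
})

test_that("planes are spaced equally by arclength with tangent normals", {
  line <- cbind(0, 0, seq(0, 0.1, length.out = 11))
  ps <- make_planes(line, n = 38)
  expect_equal(nrow(ps$origin), 38)
  expect_equal(ps$normal, matrix(rep(c(0, 0, 1), each = 38), 38, 3))
  expect_equal(diff(ps$arclength), rep(0.1 / 37, 37))
  # helix: tangents match the analytic derivative direction
  tt <- seq(0, 4 * pi, length.out = 4001)
  helix <- cbind(cos(tt), sin(tt), 0.2 * tt)
  hp <- make_planes(helix, n = 10)
  for (i in c(2, 5, 9)) {
    s <- hp$arclength[i]
    t_par <- s / sqrt(1 + 0.04)   # arclength ds = sqrt(1 + b^2) dt
    tan_true <- c(-sin(t_par), cos(t_par), 0.2) / sqrt(1.04)
    expect_equal(unname(hp$normal[i, ]), tan_true, tolerance = 1e-3)
  }
  expect_error(make_planes(line, n = 0), "at least 1")
  expect_error(make_planes(line[1, , drop = FALSE]), "at least 2")
})

test_that("plane-mean swirl recovers the vortex rotation rate anywhere", {
  pts <- cartesian_lattice(c(6, 6, 8), 2e-3)
  f <- rigid_vortex_field(2.0, c(0, 0, 1), pts, times = 0)
  J <- velocity_gradient(f, method = "structured")
  ss <- swirling_strength(J)
  for (z0 in c(0.002, 0.007, 0.012)) {
    m <- plane_mean_ss(f, c(0.005, 0.005, z0), c(0, 0, 1), 1.1e-3, ss = ss)
    expect_equal(m, 2.0, tolerance = 1e-6)
  }
  # pure shear: real spectrum, zero swirl
  shear <- linear_field(matrix(c(0, 0, 0, 1, 0, 0, 0, 0, 0), 3, 3), pts)
  Js <- velocity_gradient(shear, method = "structured")
  expect_equal(max(swirling_strength(Js)), 0)
  # empty slab is a warning + missing value
  expect_warning(
    m2 <- plane_mean_ss(f, c(0, 0, 1), c(0, 0, 1), 1e-6, ss = ss),
    "no field points")
  expect_true(is.na(m2))
})

test_that("axial Womersley flow carries no swirl", {
  ws <- womersley_spec(steady_gradient = 80, n_radial = 6, n_theta = 8,
                       n_axial = 3, n_steps = 4)
  f <- womersley_pipe(ws)$volume
  J <- velocity_gradient(f, method = "knn_lsq", k = 12)
  expect_equal(max(swirling_strength(J)), 0)
})

test_that("TASS is the trapezoidal time average of plane-mean swirl", {
  tt <- seq(0, 1, length.out = 2001)
  expect_equal(tass(rep(3, 2001), tt), 3)
  expect_equal(tass(abs(sin(pi * tt)) * 5, tt), 2 * 5 / pi, tolerance = 1e-5)
  expect_equal(tass(rep(0, 2001), tt), 0)
  m <- rbind(rep(1, 2001), abs(sin(pi * tt)))
  expect_equal(tass(m, tt), c(1, 2 / pi), tolerance = 1e-5)
})

test_that("normalised mean swirl is scale-free with unit peak", {
  ssm <- rbind(c(1, 3, 2), c(1, 3, 2))   # identical planes
  nm <- normalised_mean_ss(ssm)
  expect_equal(nm, c(1, 3, 2) / 3)
  expect_equal(max(nm), 1)
  expect_equal(normalised_mean_ss(matrix(5, 1, 1)), 1)   # single time
  expect_error(normalised_mean_ss(matrix(0, 3, 4)), "identically zero")
  # point-wise dominance is preserved by the unnormalised mean
  a <- matrix(stats::runif(12, 1, 2), 3, 4)
  b <- a - 0.5
  expect_true(all(colMeans(a) >= colMeans(b)))
})

test_that("swirl profile recovers constant rotation across planes and time", {
  pts <- cartesian_lattice(c(5, 5, 7), 2e-3)
  f <- rigid_vortex_field(1.5, c(0, 0, 1), pts,
                          times = seq(0, 0.731, length.out = 4))
  f$period <- 0.731
  planes <- make_planes(cbind(0.004, 0.004, seq(0, 0.012, length.out = 5)),
                        n = 5)
  prof <- swirl_profile(f, planes, method = "structured")
  expect_equal(unname(prof$tass), rep(1.5, 5), tolerance = 1e-9)
  expect_equal(unname(prof$normalised_mean_ss), rep(1, 4))
})
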