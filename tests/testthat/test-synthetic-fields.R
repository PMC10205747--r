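test_that("steady spec reproduces Poiseuille flow and its wall shear", {
  G <- 100; R <- 0.01; mu <- 0.0035
  ws <- womersley_spec(radius = R, viscosity = mu, steady_gradient = G)
  f <- womersley_pipe(ws)
  rr <- sqrt(f$volume$points[, 1]^2 + f$volume$points[, 2]^2)
  expect_equal(f$volume$vectors[1, , 3], G * (R^2 - rr^2) / (4 * mu),
               tolerance = 1e-12)
  expect_equal(unname(field_magnitudes(f$wall)[1, ]),
               rep(G * R / 2, nrow(f$wall$points)))
  expect_true(all(f$wall$normals[, 3] == 0))
  expect_equal(rowSums(f$wall$normals * f$wall$points[, 1:3]) / R,
               rep(-1, nrow(f$wall$points)))   # inward normals
})

test_that("low-frequency harmonic is quasi-steady within 1%", {
  R <- 0.002; mu <- 0.0035; rho <- 1056
  om <- 0.02   # alpha ~ 0.16: deep quasi-steady regime
  ws <- womersley_spec(radius = R, viscosity = mu, density = rho,
                       steady_gradient = 0,
                       harmonics = data.frame(omega = om, amplitude = 500,
                                              phase = 0))
  tt <- seq(0, 2 * pi / om, length.out = 13)
  rr <- seq(0, R, length.out = 9)
  u <- womersley_velocity(rr, tt, ws)
  quasi <- outer((R^2 - rr^2) / (4 * mu), 500 * cos(om * tt))
  expect_lt(max(abs(u - quasi)) / max(abs(quasi)), 0.01)
})

test_that("analytic wall shear matches a radial finite difference of u", {
  ws <- womersley_spec(radius = 0.01, viscosity = 0.0035,
                       steady_gradient = 50,
                       harmonics = data.frame(omega = 2 * pi / 0.731,
                                              amplitude = 150, phase = 0.4))
  tt <- seq(0, 0.731, length.out = 7)
  tau <- womersley_wall_shear(tt, ws)
  fd_tau <- function(h) {
    u <- womersley_velocity(c(0.01 - 2 * h, 0.01 - h, 0.01), tt, ws)
    dudr <- (3 * u[3, ] - 4 * u[2, ] + u[1, ]) / (2 * h)   # O(h^2) one-sided
    -0.0035 * dudr
  }
  err1 <- max(abs(fd_tau(2e-4) - tau))
  err2 <- max(abs(fd_tau(1e-4) - tau))
  expect_lt(err1 / max(abs(tau)), 1e-2)
  expect_gt(err1 / err2, 3)   # second-order convergence
})

test_that("generated series are exactly periodic sample-for-sample", {
  ws <- womersley_spec(steady_gradient = 20,
                       harmonics = data.frame(omega = 2 * pi, amplitude = 80,
                                              phase = 1))
  f <- womersley_pipe(ws)
  nt <- length(f$volume$times)
  expect_identical(f$volume$vectors[1, , ], f$volume$vectors[nt, , ])
  expect_identical(f$wall$vectors[1, , ], f$wall$vectors[nt, , ])
})

test_that("excessive Womersley number is refused", {
  expect_error(
    womersley_spec(radius = 0.05,
                   harmonics = data.frame(omega = 500, amplitude = 1,
                                          phase = 0)),
    "exceeds the supported cap")
})

test_that("rigid vortex field encodes solid-body rotation", {
  pts <- cartesian_lattice(c(5, 5, 5), 1e-3)
  f <- rigid_vortex_field(2, c(0, 0, 1), pts, times = c(0, 0.1))
  # v = omega z_hat x x: vx = -omega y, vy = omega x
  expect_equal(f$vectors[1, , 1], -2 * pts[, 2])
  expect_equal(f$vectors[1, , 2], 2 * pts[, 1])
  expect_equal(f$vectors[1, , 3], rep(0, nrow(pts)))
  expect_identical(f$vectors[1, , ], f$vectors[2, , ])
  f0 <- rigid_vortex_field(0, c(0, 0, 1), pts)
  expect_true(all(f0$vectors == 0))
  expect_error(rigid_vortex_field(1, c(0, 0, 0), pts), "nonzero")
  expect_error(rigid_vortex_field(1, c(0, 0, 2), pts), "unit length")
})

test_that("branching network conserves mass and is deterministic", {
  q <- flow_waveform(inlet_area = 4.9e-4, unit = "ml/s")
  splits <- c(BT = 0.3166, LCC = 0.0960, LS = 0.1580, DA = 0.4123)
  net <- branching_network_flows(q, splits)
  expect_named(net, names(splits))
  for (nm in names(splits))
    expect_equal(net[[nm]]$value, splits[[nm]] * q$value)
  expect_equal(attr(net, "residual_fraction"), 1 - sum(splits))
  # splits summing to one: outlets add back to the inlet point-wise
  net4 <- branching_network_flows(q, c(a = 0.25, b = 0.25, c = 0.25,
                                       d = 0.25))
  total <- Reduce(`+`, lapply(net4, function(s) s$value))
  expect_equal(total, q$value, tolerance = 1e-14)
  # determinism under a seed, with noise on
  n1 <- branching_network_flows(q, splits, noise_sd = 0.01, seed = 9)
  n2 <- branching_network_flows(q, splits, noise_sd = 0.01, seed = 9)
  expect_identical(n1$DA$value, n2$DA$value)
  expect_error(branching_network_flows(q, c(a = -0.1, b = 0.5)),
               "nonnegative")
  expect_error(branching_network_flows(q, c(a = 0.7, b = 0.5)), "> 1")
  expect_error(branching_network_flows(q, c(0.5, 0.3)), "named")
})

test_that("noise injection is reproducible and correctly scaled", {
  s <- hemo_series(seq(0, 1, length.out = 20001), rep(5, 20001))
  expect_identical(add_noise(s, 0), s)
  a <- add_noise(s, 0.05, seed = 4)
  b <- add_noise(s, 0.05, seed = 4)
  expect_identical(a$value, b$value)
  cv <- stats::sd(a$value) / mean(a$value)
  n <- nrow(s)
  expect_lt(abs(cv - 0.05), 3 * 0.05 / sqrt(2 * n))
  # field variant
  pts <- cartesian_lattice(c(4, 4, 4), 1e-3)
  f <- rigid_vortex_field(1, c(0, 0, 1), pts)
  fn <- add_noise(f, 0.01, seed = 2)
  expect_identical(add_noise(f, 0.01, seed = 2)$vectors, fn$vectors)
  expect_false(identical(fn$vectors, f$vectors))
})
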