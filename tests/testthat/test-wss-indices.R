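test_that("TAWSS averages the shear magnitude over the cycle", {
  expect_equal(tawss(steady_wall_series(tau = 2)), 2)
  # alternating direction, constant magnitude except at switch samples
  alt <- alternating_wall_series(tau = 3, n = 81)
  expect_equal(tawss(alt), 3, tolerance = 0.05)
})

test_that("OSI separates steady from fully reversing shear", {
  expect_equal(osi(steady_wall_series(tau = 2)), 0)
  expect_equal(osi(alternating_wall_series(tau = 3)), 0.5)
  # no shear at all: OSI defined as 0
  zero <- steady_wall_series(tau = 0)
  expect_equal(osi(zero), 0)
  expect_equal(tawss(zero), 0)
})

test_that("Womersley wall series matches a 10x-refined quadrature oracle", {
  ws <- womersley_spec(radius = 0.01, viscosity = 0.0035,
                       steady_gradient = 30,
                       harmonics = data.frame(omega = 2 * pi / 0.731,
                                              amplitude = 800, phase = 0.3),
                       n_steps = 366)
  f <- womersley_pipe(ws)
  ta <- tawss(f$wall)
  os <- osi(f$wall)
  # reversing configuration: oscillatory part dominates the steady part
  expect_gt(max(os), 0.05)
  tt_fine <- seq(0, ws$period, length.out = 10 * ws$n_steps + 1)
  tau_fine <- womersley_wall_shear(tt_fine, ws)
  ta_oracle <- oracle_trapz(tt_fine, abs(tau_fine)) / ws$period
  mean_oracle <- abs(oracle_trapz(tt_fine, tau_fine)) / ws$period
  os_oracle <- 0.5 * (1 - mean_oracle / ta_oracle)
  expect_equal(unname(ta[1]), ta_oracle, tolerance = 1e-3)
  expect_equal(unname(os[1]), os_oracle, tolerance = 1e-3)
})

test_that("HOLMES is the element-wise product TAWSS * (0.5 - OSI)", {
  expect_equal(holmes(2, 0), 1)
  expect_equal(holmes(2, 0.5), 0)
  set.seed(11)
  ta <- stats::rexp(50, 1)
  os <- stats::runif(50, 0, 0.5)
  h <- holmes(ta, os)
  for (i in seq_along(ta)) expect_equal(h[i], ta[i] * (0.5 - os[i]))
  expect_error(holmes(1:3, 1:2), "aligned")
})

test_that("index bounds hold on arbitrary random wall series", {
  for (seed in 1:5) {
    w <- random_wall_series(n_pts = 8, n_t = 25, seed = seed)
    ta <- tawss(w); os <- osi(w); hm <- holmes(ta, os)
    expect_true(all(ta >= 0))
    expect_true(all(os >= 0 & os <= 0.5))
    expect_true(all(hm >= -1e-12 & hm <= 0.5 * ta + 1e-12))
  }
  # equality HOLMES = 0.5 TAWSS iff OSI = 0
  st <- steady_wall_series(tau = 4)
  expect_equal(holmes(tawss(st), osi(st)), 0.5 * tawss(st))
})

test_that("halving the time step moves smooth indices by < 0.5%", {
  mk <- function(n) womersley_pipe(
    womersley_spec(steady_gradient = 25,
                   harmonics = data.frame(omega = 2 * pi, amplitude = 120,
                                          phase = 0),
                   n_steps = n))$wall
  ta1 <- tawss(mk(40)); ta2 <- tawss(mk(80))
  os1 <- osi(mk(40)); os2 <- osi(mk(80))
  expect_lt(max(abs(ta1 - ta2) / ta2), 0.005)
  expect_lt(max(abs(os1 - os2)), 0.005 * 0.5)
})

test_that("multi-cycle series use the final cycle and short ones error", {
  ws <- womersley_spec(steady_gradient = 40, n_steps = 20)
  one <- womersley_pipe(ws)$wall
  nt <- length(one$times)
  vec2 <- array(0, dim = c(2 * nt - 1, nrow(one$points), 3))
  vec2[1:nt, , ] <- one$vectors
  vec2[(nt + 1):(2 * nt - 1), , ] <- one$vectors[-1, , , drop = FALSE]
  two <- one
  two$times <- c(one$times, one$times[-1] + ws$period)
  two$vectors <- vec2
  expect_equal(tawss(two), tawss(one))
  short <- one
  short$times <- one$times[1:5]
  short$vectors <- one$vectors[1:5, , , drop = FALSE]
  expect_error(tawss(short), "shorter than one period")
  vol <- womersley_pipe(ws)$volume
  expect_error(tawss(vol), "wall_shear")
})

test_that("percent-difference maps bin the changed-node fractions", {
  b <- rep(1, 10)
  same <- percent_difference_map(b, b)
  expect_equal(same$percent, rep(0, 10))
  up <- percent_difference_map(1.1 * b, b)
  expect_equal(up$percent, rep(10, 10), tolerance = 1e-12)
  # 30% of nodes shifted by +12%: binned summary flags exactly those
  n <- 200
  a <- rep(1, n)
  a[1:60] <- 1.12
  pd <- percent_difference_map(a, rep(1, n))
  expect_equal(unname(pd$summary[["beyond_10"]]), 0.3)
  expect_equal(unname(pd$summary[["beyond_5"]]), 0.3)
  expect_equal(unname(pd$summary[["beyond_20"]]), 0)
  # masking: zero-denominator nodes excluded, all-masked errors
  pm <- percent_difference_map(c(1, 2), c(0, 1))
  expect_true(pm$masked[1] && !pm$masked[2])
  expect_true(is.na(pm$percent[1]))
  expect_error(percent_difference_map(c(1, 2), c(0, 0)), "all nodes masked")
  expect_error(percent_difference_map(1:3, 1:2), "aligned")
})
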