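da_params <- function() reference_windkessel()$DA   # R=1.03, r=0.16, C=1.36

constant_flow <- function(q = 20, period = 0.731, n = 80) {
  hemo_series(seq(0, period, length.out = n), rep(q, n), unit = "ml/s",
              period = period)
}

half_sine_flow <- function(mean_q = 20, dt = 0.002) {
  ct <- patient_timing()
  v_mean <- 2 * ct$peak_velocity * ct$ejection_duration / (pi * ct$period)
  flow_waveform(ct, inlet_area = mean_q * 1e-6 / v_mean, dt = dt,
                unit = "ml/s")
}

test_that("reference outlet parameter fixture is complete", {
  ref <- reference_windkessel()
  expect_setequal(names(ref), c("BT", "LCC", "LS", "DA"))
  expect_equal(ref$DA$R, 1.03)
  expect_equal(ref$BT$C, 0.41)
  expect_equal(ref$LCC$r, 0.50)
  expect_equal(ref$LS$C, 0.38)
})

test_that("constant outflow settles on the resistive fixed point", {
  p <- da_params()
  pr <- wk_simulate(constant_flow(20), p, p_init = 40, n_cycles = 200,
                    tol = 1e-5)
  expect_equal(max(abs(pr$value - (p$p_venous + 20 * (p$R + p$r)))) /
                 (20 * (p$R + p$r)), 0, tolerance = 1e-3)
})

test_that("zero-flow relaxation follows the RC exponential", {
  p <- da_params()
  h <- 0.002
  x <- numeric(400)
  x[1] <- 50   # capacitor 50 mmHg above venous pressure
  for (i in 2:400) x[i] <- hemoflow:::wk_step(x[i - 1], 0, 0, h, p$R, p$C)
  tt <- (seq_along(x) - 1) * h
  expect_equal(x, 50 * exp(-tt / (p$R * p$C)), tolerance = 1e-12)
  # recovered decay constant within 0.1%
  tau_hat <- -1 / stats::coef(stats::lm(log(x) ~ tt))[["tt"]]
  expect_equal(tau_hat, p$R * p$C, tolerance = 1e-3)
})

test_that("exponential update matches an adaptive stiff ODE oracle", {
  p <- da_params()
  q <- half_sine_flow(20)
  mine <- wk_simulate(q, p, n_cycles = 100, tol = 1e-4)
  # independent route: lsoda on the RCR ODE with periodic interpolated flow
  qf <- stats::approxfun(q$time_s, q$value)
  qper <- function(t) qf(t %% 0.731)
  rhs <- function(t, y, parms)
    list((qper(t) - (y - p$p_venous) / p$R) / p$C)
  n_burn <- 40
  times <- c(outer(q$time_s, 0.731 * (0:(n_burn - 1)), `+`))
  sol <- deSolve::lsoda(c(pc = p$p_venous + 20 * (p$R + p$r)), times, rhs,
                        NULL, rtol = 1e-10, atol = 1e-10)
  last <- sol[(nrow(sol) - nrow(q) + 1):nrow(sol), "pc"]
  oracle_p <- last + q$value * p$r
  expect_lt(max(abs(mine$value - oracle_p)), 0.1)
})

test_that("steady-state pressure is linear in flow and mean is C-free", {
  p <- da_params()
  q1 <- half_sine_flow(15)
  q2 <- hemo_series(q1$time_s, 2 * q1$value, unit = "ml/s", period = 0.731)
  p1 <- wk_simulate(q1, p, n_cycles = 200, tol = 1e-5)
  p2 <- wk_simulate(q2, p, n_cycles = 200, tol = 1e-5)
  expect_equal(p2$value - p$p_venous, 2 * (p1$value - p$p_venous),
               tolerance = 1e-3)
  # cycle-mean pressure = pv + mean(Q) (R + r), independent of C (0.1%)
  for (C in c(0.4, 1.36, 4)) {
    pc <- windkessel_params(p$R, p$r, C, p$p_venous)
    pr <- wk_simulate(q1, pc, n_cycles = 300, tol = 1e-5)
    mean_p <- oracle_trapz(pr$time_s, pr$value) / 0.731
    expect_equal(mean_p, p$p_venous + 15 * (p$R + p$r), tolerance = 1e-3)
  }
})

test_that("pulse pressure shrinks strictly as compliance grows", {
  p <- da_params()
  q <- half_sine_flow(20)
  pulse <- sapply(c(0.5, 1, 2, 4), function(C) {
    pr <- wk_simulate(q, windkessel_params(p$R, p$r, C), n_cycles = 200,
                      tol = 1e-4)
    diff(range(pr$value))
  })
  expect_true(all(diff(pulse) < 0))
})

test_that("tuning reaches the 120/77.5 mmHg patient targets", {
  fit <- wk_tune(half_sine_flow(20), systolic = 120, diastolic = 77.5)
  expect_lt(abs(fit$achieved[["systolic"]] - 120), 0.5)
  expect_lt(abs(fit$achieved[["dia"]] - 77.5), 0.5)
  expect_equal(unname(coef(fit)[["R"]] + coef(fit)[["r"]]), fit$R_total)
  # methods behave
  expect_named(coef(fit), c("R", "r", "C"))
  expect_lt(max(abs(residuals(fit))), 0.5)
  expect_output(print(fit), "Tuned three-element Windkessel")
  expect_output(summary(fit), "Achieved systolic")
  pred <- predict(fit)
  expect_s3_class(pred, "hemo_series")
  sims <- simulate(fit, nsim = 2, seed = 3, sd = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$value, sims[[2]]$value))
})

test_that("re-tuning at the achieved pressures returns the same model", {
  q <- half_sine_flow(20)
  fit1 <- wk_tune(q, 120, 77.5, tol = 0.01)
  fit2 <- wk_tune(q, fit1$achieved[["systolic"]], fit1$achieved[["dia"]],
                  tol = 0.01)
  expect_equal(coef(fit2), coef(fit1), tolerance = 0.02)
})

test_that("unreachable pulse-pressure targets raise a tuning error", {
  q <- half_sine_flow(20)
  expect_error(wk_tune(q, systolic = 80.2, diastolic = 80.0),
               "unreachable|infeasible")
  expect_error(wk_tune(q, systolic = 70, diastolic = 90), "targets must")
  qm <- oracle_trapz(q$time_s, q$value) / (q$time_s[nrow(q)] - q$time_s[1])
  q0 <- hemo_series(q$time_s, q$value - qm, unit = "ml/s")
  expect_error(wk_tune(q0, 120, 77.5), "positive cycle mean")
})

test_that("non-convergent simulation reports the residual", {
  p <- windkessel_params(R = 50, r = 0.1, C = 10)   # RC = 500 s
  q <- half_sine_flow(20)
  expect_error(wk_simulate(q, p, p_init = 300, n_cycles = 3),
               "not periodic")
})
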