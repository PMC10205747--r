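#' Three-element Windkessel (RCR) outlet parameters
#'
#' Lumped outlet model relating outflow \eqn{Q(t)} to outlet pressure
#' \eqn{P(t)} through a proximal resistance \eqn{r}, a distal resistance
#' \eqn{R} and a compliance \eqn{C}:
#' \deqn{C \frac{dP_c}{dt} = Q - \frac{P_c - P_v}{R}, \qquad P = P_c + Q r,}
#' with \eqn{P_v} a distal venous reference pressure. Clinical units are used
#' throughout this module: mmHg, ml/s, so resistances are mmHg s/ml and the
#' compliance ml/mmHg.
#'
#' @param R distal resistance, mmHg s/ml (> 0).
#' @param r proximal (characteristic) resistance, mmHg s/ml (>= 0).
#' @param C compliance, ml/mmHg (> 0).
#' @param p_venous distal reference pressure, mmHg.
#' @return an object of class `windkessel_params`.
#' @seealso [reference_windkessel()] for the tuned four-outlet aortic set.
#' @export
windkessel_params <- function(R, r, C, p_venous = 0) {
  if (!all(is.finite(c(R, r, C, p_venous))))
    stop("Windkessel parameters must be finite", call. = FALSE)
  if (R <= 0 || C <= 0 || r < 0)
    stop("require R > 0, C > 0, r >= 0", call. = FALSE)
  structure(list(R = R, r = r, C = C, p_venous = p_venous),
            class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf("<windkessel_params> R = %g, r = %g mmHg s/ml; C = %g ml/mmHg; Pv = %g mmHg\n",
              x$R, x$r, x$C, x$p_venous))
  invisible(x)
}

#' Tuned Windkessel parameters for the four aortic outlets
#'
#' Reference parameter sets for the brachiocephalic trunk (BT), left common
#' carotid (LCC), left subclavian (LS) and distal aorta (DA) outlets of the
#' post-traumatic aortic model, as tuned against the patient's 120/77.5 mmHg
#' pressure targets.
#'
#' @return named list of [windkessel_params()] with names BT, LCC, LS, DA.
#' @examples
#' reference_windkessel()$DA$R   # 1.03 mmHg s/ml
#' @export
reference_windkessel <- function() {
  list(
    BT  = windkessel_params(R = 9.98, r = 0.03, C = 0.41),
    LCC = windkessel_params(R = 7.62, r = 0.50, C = 0.53),
    LS  = windkessel_params(R = 6.01, r = 0.12, C = 0.38),
    DA  = windkessel_params(R = 1.03, r = 0.16, C = 1.36)
  )
}

# Advance the capacitor pressure x = P_c - P_v over one sampling interval of
# length h with the outflow varying linearly from q0 to q1. Exact solution of
# the linear ODE (no stiffness restriction on h):
#   x(h) = x0 e^{-h/tau} + R q0 (1 - e^{-h/tau}) + R s (h - tau (1 - e^{-h/tau}))
# with tau = R C and s = (q1 - q0)/h.
wk_step <- function(x0, q0, q1, h, R, C) {
  tau <- R * C
  e <- exp(-h / tau)
  x0 * e + R * q0 * (1 - e) + R * (q1 - q0) / h * (h - tau * (1 - e))
}

#' Simulate Windkessel outlet pressure to periodic steady state
#'
#' Integrates the RCR dynamics for a periodic outflow waveform, cycle by
#' cycle, using the exact exponential update of the linear ODE per sampling
#' interval (outflow held piecewise linear), so the solver-native 0.002 s
#' grid poses no stiffness problem. Periodic steady state is declared when
#' the pressure over one cycle differs from the previous cycle by less than
#' `tol` everywhere; at least `burn_in` cycles are always run.
#'
#' @param flow a [hemo_series()] of outflow in ml/s covering exactly one
#'   cycle (first and last samples one period apart).
#' @param params a [windkessel_params()].
#' @param p_init initial outlet pressure, mmHg; default is the steady mean
#'   `p_venous + mean(Q) (R + r)`, which makes convergence fast.
#' @param n_cycles maximum number of cycles to integrate (>= 2).
#' @param tol periodic steady-state tolerance, mmHg (max abs cycle-to-cycle
#'   pressure change).
#' @param burn_in minimum cycles before the steady-state test is applied.
#' @param strict error (rather than warn) if steady state is not reached
#'   within `n_cycles`.
#' @return a [hemo_series()] of outlet pressure in mmHg over the final cycle,
#'   with attributes `converged` (logical), `residual` (mmHg) and `cycles`
#'   (number of cycles integrated).
#' @examples
#' q <- flow_waveform(inlet_area = 1e-4, unit = "ml/s")
#' p <- wk_simulate(q, reference_windkessel()$DA)
#' range(p$value)
#' @export
wk_simulate <- function(flow, params, p_init = NULL, n_cycles = 50,
                        tol = 0.05, burn_in = 5, strict = TRUE) {
  stopifnot(inherits(flow, "hemo_series"), inherits(params, "windkessel_params"))
  if (n_cycles < 2) stop("`n_cycles` must be at least 2", call. = FALSE)
  tt <- flow$time_s - flow$time_s[1]
  q <- flow$value
  n <- length(tt)
  if (n < 3) stop("flow series too short to integrate", call. = FALSE)
  h <- diff(tt)
  R <- params$R; r <- params$r; C <- params$C; pv <- params$p_venous
  q_mean <- trapz(tt, q) / tt[n]
  if (is.null(p_init)) p_init <- pv + q_mean * (R + r)

  # state x = P_c - P_v; initial capacitor pressure from the requested
  # initial outlet pressure at the first sample
  x <- (p_init - q[1] * r) - pv
  p_prev <- rep(NA_real_, n)
  converged <- FALSE
  residual <- Inf
  cyc <- 0L
  for (cyc in seq_len(n_cycles)) {
    p_cycle <- numeric(n)
    p_cycle[1] <- pv + x + q[1] * r
    for (i in seq_len(n - 1)) {
      x <- wk_step(x, q[i], q[i + 1], h[i], R, C)
      p_cycle[i + 1] <- pv + x + q[i + 1] * r
    }
    if (cyc > 1) residual <- max(abs(p_cycle - p_prev))
    p_prev <- p_cycle
    if (cyc >= burn_in && residual < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    msg <- sprintf("Windkessel pressure not periodic after %d cycles (residual %.3g mmHg > %.3g)",
                   cyc, residual, tol)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out <- hemo_series(tt, p_prev, unit = "mmHg", period = tt[n])
  attr(out, "converged") <- converged
  attr(out, "residual") <- residual
  attr(out, "cycles") <- cyc
  out
}

#' Tune a three-element Windkessel to systolic/diastolic pressure targets
#'
#' Finds RCR parameters whose periodic steady-state pressure response to a
#' given periodic outflow attains prescribed systolic (cycle maximum) and
#' diastolic (cycle minimum) pressures. The procedure is the standard
#' two-stage RCR calibration:
#'
#' 1. The total resistance is fixed from the mean pressure balance,
#'    \eqn{R + r = (\mathrm{MAP} - P_v) / \bar Q}, with the classic estimate
#'    \eqn{\mathrm{MAP} = P_{dia} + (P_{sys} - P_{dia})/3}; the proximal
#'    share defaults to `r_fraction = 0.056` of the total (characteristic-
#'    impedance convention).
#' 2. The compliance is bracketed and bisected on simulated pulse pressure,
#'    then a damped Newton iteration on `(r_fraction, C)` (finite-difference
#'    Jacobian, total resistance held fixed) polishes both extremes onto the
#'    targets.
#'
#' @param flow a [hemo_series()] of outflow in ml/s covering one cycle, with
#'   positive cycle mean.
#' @param systolic,diastolic target cycle-max / cycle-min pressures, mmHg.
#' @param p_venous distal reference pressure, mmHg.
#' @param r_fraction initial proximal share of total resistance, in [0, 0.5).
#' @param tol target tolerance, mmHg, on both extremes (default 0.05 so the
#'   result sits well inside a 0.5 mmHg acceptance band).
#' @param max_iter Newton iteration cap.
#' @param sim_tol periodic steady-state tolerance passed to [wk_simulate()].
#' @return an object of class `windkessel_fit`: the tuned
#'   [windkessel_params()] plus the achieved pressures, the steady-cycle
#'   pressure waveform, and the iteration trace. Methods: `print`, `summary`,
#'   `coef`, `predict`, `simulate`, `residuals`, `plot`.
#' @examples
#' q <- flow_waveform(inlet_area = 2e-4, unit = "ml/s")  # ~ 16 ml/s mean
#' fit <- wk_tune(q, systolic = 120, diastolic = 77.5)
#' coef(fit)
#' residuals(fit)   # mmHg miss on each target
#' @export
wk_tune <- function(flow, systolic = 120, diastolic = 77.5, p_venous = 0,
                    r_fraction = 0.056, tol = 0.05, max_iter = 40,
                    sim_tol = 0.01) {
  stopifnot(inherits(flow, "hemo_series"))
  if (!(systolic > diastolic && diastolic > p_venous))
    stop("targets must satisfy systolic > diastolic > p_venous", call. = FALSE)
  tt <- flow$time_s - flow$time_s[1]
  q_mean <- trapz(tt, flow$value) / tt[length(tt)]
  if (q_mean <= 1e-9 * max(abs(flow$value), 1e-12))
    stop("flow must have a positive cycle mean to carry a mean pressure",
         call. = FALSE)

  map <- diastolic + (systolic - diastolic) / 3
  R_tot <- (map - p_venous) / q_mean

  extremes <- function(rf, C) {
    par <- windkessel_params(R = (1 - rf) * R_tot, r = rf * R_tot, C = C,
                             p_venous = p_venous)
    p <- wk_simulate(flow, par, n_cycles = 200, tol = sim_tol, strict = TRUE)
    c(sys = max(p$value), dia = min(p$value))
  }

  # --- stage 2a: bracket and bisect C on pulse pressure at fixed r_fraction
  pp_target <- systolic - diastolic
  pulse_of <- function(C) diff(rev(extremes(r_fraction, C)))  # sys - dia
  C_lo <- 0.01; C_hi <- 10
  # widen the bracket if needed: pulse pressure decreases with C
  while (pulse_of(C_hi) > pp_target && C_hi < 1e4) C_hi <- C_hi * 4
  while (pulse_of(C_lo) < pp_target && C_lo > 1e-5) C_lo <- C_lo / 4
  f_lo <- pulse_of(C_lo) - pp_target
  f_hi <- pulse_of(C_hi) - pp_target
  if (f_lo < 0 || f_hi > 0)
    stop(sprintf(paste0("pulse-pressure target %.1f mmHg unreachable for any ",
                        "compliance (attainable range [%.1f, %.1f] mmHg): ",
                        "targets infeasible for this flow"),
                 pp_target, pulse_of(C_hi) , pulse_of(C_lo)), call. = FALSE)
  for (i in 1:40) {
    C_mid <- sqrt(C_lo * C_hi)
    if (pulse_of(C_mid) - pp_target > 0) C_lo <- C_mid else C_hi <- C_mid
    if (C_hi / C_lo < 1 + 1e-3) break
  }
  C_cur <- sqrt(C_lo * C_hi)
  rf_cur <- r_fraction

  # --- stage 2b: damped Newton on (r_fraction, C), total resistance fixed
  trace <- list()
  val <- extremes(rf_cur, C_cur)
  for (it in seq_len(max_iter)) {
    err <- c(val[["sys"]] - systolic, val[["dia"]] - diastolic)
    trace[[it]] <- c(iter = it, r_fraction = rf_cur, C = C_cur,
                     sys = val[["sys"]], dia = val[["dia"]])
    if (max(abs(err)) < tol) break
    d_rf <- max(1e-4, 0.02 * rf_cur)
    d_C <- 0.02 * C_cur
    v_rf <- extremes(min(rf_cur + d_rf, 0.49), C_cur)
    v_C <- extremes(rf_cur, C_cur + d_C)
    J <- cbind((v_rf - val) / (min(rf_cur + d_rf, 0.49) - rf_cur),
               (v_C - val) / d_C)
    step <- tryCatch(solve(J, -err), error = function(e) NULL)
    if (is.null(step))
      stop("tuning Jacobian singular: targets infeasible or flow degenerate",
           call. = FALSE)
    lam <- 1
    repeat {
      rf_new <- min(max(rf_cur + lam * step[1], 0), 0.49)
      C_new <- max(C_cur + lam * step[2], 1e-5)
      val_new <- extremes(rf_new, C_new)
      err_new <- c(val_new[["sys"]] - systolic, val_new[["dia"]] - diastolic)
      if (sum(err_new^2) < sum(err^2) || lam < 1 / 64) break
      lam <- lam / 2
    }
    rf_cur <- rf_new; C_cur <- C_new; val <- val_new
  }
  err <- c(val[["sys"]] - systolic, val[["dia"]] - diastolic)
  if (max(abs(err)) >= 0.5)
    stop(sprintf("tuning did not reach targets (miss: sys %+.2f, dia %+.2f mmHg)",
                 err[1], err[2]), call. = FALSE)

  params <- windkessel_params(R = (1 - rf_cur) * R_tot, r = rf_cur * R_tot,
                              C = C_cur, p_venous = p_venous)
  pressure <- wk_simulate(flow, params, n_cycles = 200, tol = sim_tol)
  structure(list(params = params, flow = flow,
                 targets = c(systolic = systolic, diastolic = diastolic),
                 achieved = c(systolic = val[["sys"]], dia = val[["dia"]]),
                 mean_flow = q_mean, map_estimate = map, R_total = R_tot,
                 r_fraction = rf_cur, pressure = pressure,
                 trace = do.call(rbind, trace)),
            class = "windkessel_fit")
}

#' @export
print.windkessel_fit <- function(x, ...) {
  cat("Tuned three-element Windkessel\n")
  cat(sprintf("  R = %.4f  r = %.4f mmHg s/ml   C = %.4f ml/mmHg\n",
              x$params$R, x$params$r, x$params$C))
  cat(sprintf("  pressure: %.2f / %.2f mmHg (targets %.1f / %.1f)\n",
              x$achieved[1], x$achieved[2], x$targets[1], x$targets[2]))
  invisible(x)
}

#' @export
summary.windkessel_fit <- function(object, ...) {
  x <- object
  cat("Three-element Windkessel tuning\n\n")
  cat(sprintf("Mean outflow          : %.3f ml/s\n", x$mean_flow))
  cat(sprintf("MAP estimate (1/3 rule): %.2f mmHg\n", x$map_estimate))
  cat(sprintf("Total resistance R + r : %.4f mmHg s/ml (proximal share %.4f)\n",
              x$R_total, x$r_fraction))
  cat(sprintf("Compliance C           : %.4f ml/mmHg\n", x$params$C))
  cat(sprintf("Achieved systolic      : %.3f mmHg (target %.1f)\n",
              x$achieved[1], x$targets[1]))
  cat(sprintf("Achieved diastolic     : %.3f mmHg (target %.1f)\n",
              x$achieved[2], x$targets[2]))
  cat(sprintf("Newton iterations      : %d\n", nrow(x$trace)))
  invisible(x)
}

#' @export
coef.windkessel_fit <- function(object, ...) {
  with(object$params, c(R = R, r = r, C = C))
}

#' @export
residuals.windkessel_fit <- function(object, ...) {
  c(systolic = unname(object$achieved[1] - object$targets[1]),
    diastolic = unname(object$achieved[2] - object$targets[2]))
}

#' Predict the periodic steady-state pressure response of a tuned Windkessel
#'
#' @param object a `windkessel_fit`.
#' @param flow optional new outflow [hemo_series()] (ml/s, one cycle);
#'   defaults to the flow the model was tuned on.
#' @param ... passed to [wk_simulate()].
#' @return pressure [hemo_series()] (mmHg) over the final cycle.
#' @export
predict.windkessel_fit <- function(object, flow = NULL, ...) {
  if (is.null(flow)) return(object$pressure)
  wk_simulate(flow, object$params, ...)
}

#' Simulate pressure responses from a tuned Windkessel
#'
#' Returns `nsim` periodic steady-state pressure waveforms; with `sd > 0`
#' each is perturbed by i.i.d. Gaussian measurement noise.
#'
#' @param object a `windkessel_fit`.
#' @param nsim number of series.
#' @param seed optional RNG seed.
#' @param sd measurement-noise standard deviation, mmHg.
#' @param ... unused.
#' @return a list of `nsim` pressure [hemo_series()].
#' @export
simulate.windkessel_fit <- function(object, nsim = 1, seed = NULL, sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$pressure
  replicate(nsim, {
    v <- base$value + if (sd > 0) stats::rnorm(nrow(base), 0, sd) else 0
    hemo_series(base$time_s, v, unit = "mmHg", period = series_period(base))
  }, simplify = FALSE)
}

#' @export
plot.windkessel_fit <- function(x, ...) {
  p <- x$pressure
  plot(p$time_s, p$value, type = "l", xlab = "time (s)",
       ylab = "pressure (mmHg)", ...)
  graphics::abline(h = x$targets, lty = 2, col = "grey40")
  invisible(x)
}
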