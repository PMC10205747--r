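#' Carreau-Yasuda blood rheology parameters
#'
#' Five-parameter shear-thinning viscosity law interpolating between a
#' low-shear Newtonian plateau \eqn{\mu_0} and a high-shear plateau
#' \eqn{\mu_\infty}. Defaults are the standard whole-blood constants used in
#' the package's aortic simulations (Pa s and s): \eqn{\mu_0 = 0.0220},
#' \eqn{\mu_\infty = 0.0022}, \eqn{\lambda = 0.1100} s, \eqn{a = 0.6440},
#' \eqn{m = 0.3920}. Blood density (1056 kg/m^3) rides along because the
#' Womersley generator needs it together with the viscosity.
#'
#' @param mu0 zero-shear viscosity, Pa s.
#' @param mu_inf infinite-shear viscosity, Pa s (must be below `mu0`; set
#'   equal to `mu0` for a Newtonian fluid).
#' @param lambda relaxation time constant, s.
#' @param a Yasuda exponent (dimensionless, > 0).
#' @param m power-law index (dimensionless; shear-thinning for m < 1).
#' @param density fluid density, kg/m^3.
#' @return an object of class `carreau_yasuda`.
#' @export
carreau_yasuda <- function(mu0 = 0.0220, mu_inf = 0.0022, lambda = 0.1100,
                           a = 0.6440, m = 0.3920, density = 1056) {
  if (!all(is.finite(c(mu0, mu_inf, lambda, a, m, density))))
    stop("all Carreau-Yasuda parameters must be finite", call. = FALSE)
  if (mu_inf <= 0 || mu0 < mu_inf)
    stop("parameters must satisfy mu0 >= mu_inf > 0", call. = FALSE)
  if (lambda <= 0 || a <= 0)
    stop("`lambda` and `a` must be positive", call. = FALSE)
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, a = a, m = m,
                 density = density),
            class = "carreau_yasuda")
}

#' @export
print.carreau_yasuda <- function(x, ...) {
  cat("<carreau_yasuda>\n")
  cat(sprintf("  mu0 = %g Pa s, mu_inf = %g Pa s\n", x$mu0, x$mu_inf))
  cat(sprintf("  lambda = %g s, a = %g, m = %g\n", x$lambda, x$a, x$m))
  cat(sprintf("  density = %g kg/m^3\n", x$density))
  invisible(x)
}

#' Carreau-Yasuda apparent viscosity
#'
#' \deqn{\mu(\dot\gamma) = (\mu_0 - \mu_\infty)
#'   \left(1 + (\lambda\dot\gamma)^a\right)^{(m-1)/a} + \mu_\infty}
#'
#' Vectorised over `shear_rate`. For shear-thinning parameters (m < 1) the
#' value decreases monotonically from \eqn{\mu_0} at rest to the
#' \eqn{\mu_\infty} plateau. Very large \eqn{\lambda\dot\gamma} is handled in
#' log space so the high-shear limit is reached without floating overflow.
#'
#' @param shear_rate scalar or vector of shear rates, 1/s, all >= 0.
#' @param params a [carreau_yasuda()] parameter set.
#' @return apparent viscosity in Pa s, same shape as `shear_rate`.
#' @examples
#' viscosity(0)        # mu0 = 0.0220 Pa s
#' viscosity(1e12)     # ~ mu_inf = 0.0022 Pa s
#' @export
viscosity <- function(shear_rate, params = carreau_yasuda()) {
  stopifnot(inherits(params, "carreau_yasuda"))
  if (anyNA(shear_rate) || any(shear_rate < 0)) {
    bad <- which(is.na(shear_rate) | shear_rate < 0)
    stop(sprintf("negative or missing shear rate at index %d", bad[1]),
         call. = FALSE)
  }
  lg <- params$lambda * shear_rate
  expo <- (params$m - 1) / params$a
  # (1 + x^a)^e  ==  exp(e * log1p(x^a)); for huge x work with a*log(x)
  # directly: log(1 + x^a) -> a log x, exact to double precision there.
  big <- lg > 1e8
  fac <- numeric(length(lg))
  fac[!big] <- exp(expo * log1p(lg[!big]^params$a))
  fac[big] <- exp(expo * params$a * log(lg[big]))
  out <- (params$mu0 - params$mu_inf) * fac + params$mu_inf
  dim(out) <- dim(shear_rate)
  out
}

#' Apparent viscosity over a per-node shear-rate map
#'
#' Element-wise application of [viscosity()] to a field of shear rates, with
#' the offending node named when an entry is invalid.
#'
#' @param shear_rate_map numeric vector/matrix of shear rates (1/s) per node.
#' @inheritParams viscosity
#' @return viscosity map in Pa s with the shape of the input.
#' @export
viscosity_field <- function(shear_rate_map, params = carreau_yasuda()) {
  bad <- which(is.na(shear_rate_map) | shear_rate_map < 0)
  if (length(bad))
    stop(sprintf("invalid shear rate at node %d", bad[1]), call. = FALSE)
  viscosity(shear_rate_map, params)
}
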