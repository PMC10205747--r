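#' Von Mises equivalent stress
#'
#' Deviatoric scalar stress measure used to flag failure-prone regions of
#' the vessel wall:
#' \deqn{\sigma_{vm} = \sqrt{\tfrac12\left[(\sigma_{11}-\sigma_{22})^2 +
#'   (\sigma_{22}-\sigma_{33})^2 + (\sigma_{33}-\sigma_{11})^2\right] +
#'   3(\sigma_{12}^2 + \sigma_{23}^2 + \sigma_{31}^2)}.}
#' Insensitive to added hydrostatic pressure and invariant under rotation of
#' the stress tensor.
#'
#' @param stress symmetric 3 x 3 Cauchy stress tensor (any consistent unit,
#'   e.g. kPa), or an `(n, 3, 3)` array of tensors.
#' @param tol symmetry tolerance relative to the tensor magnitude.
#' @return equivalent stress(es), same unit as the input, >= 0.
#' @examples
#' von_mises(diag(c(100, 0, 0)))   # uniaxial: 100
#' von_mises(diag(c(7, 7, 7)))     # hydrostatic: 0
#' @export
von_mises <- function(stress, tol = 1e-9) {
  if (is.matrix(stress)) return(vm_one(stress, tol))
  stopifnot(is.array(stress), length(dim(stress)) == 3,
            all(dim(stress)[2:3] == c(3, 3)))
  apply(stress, 1, function(m) vm_one(matrix(m, 3, 3), tol))
}

vm_one <- function(s, tol) {
  if (any(!is.finite(s))) stop("non-finite stress entries", call. = FALSE)
  scale <- max(abs(s), 1)
  if (max(abs(s - t(s))) > tol * scale)
    stop("stress tensor is not symmetric", call. = FALSE)
  sqrt(0.5 * ((s[1, 1] - s[2, 2])^2 + (s[2, 2] - s[3, 3])^2 +
              (s[3, 3] - s[1, 1])^2) +
       3 * (s[1, 2]^2 + s[2, 3]^2 + s[1, 3]^2))
}

#' Two-parameter Mooney-Rivlin wall model
#'
#' Incompressible two-parameter Mooney-Rivlin hyperelastic law with strain
#' energy \eqn{W = A (I_1 - 3) + B (I_2 - 3)}. Defaults are the aortic-wall
#' constants used throughout the package (A = 0.1740 MPa, B = 1.8810 MPa);
#' the small-strain shear modulus is \eqn{\mu = 2 (A + B)}.
#'
#' @param A,B material constants, MPa. `A + B` must be positive.
#' @return object of class `mooney_rivlin`.
#' @export
mooney_rivlin <- function(A = 0.1740, B = 1.8810) {
  if (!all(is.finite(c(A, B))) || A + B <= 0)
    stop("require finite constants with A + B > 0", call. = FALSE)
  structure(list(A = A, B = B), class = "mooney_rivlin")
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf("<mooney_rivlin> A = %g MPa, B = %g MPa (shear modulus %g MPa)\n",
              x$A, x$B, 2 * (x$A + x$B)))
  invisible(x)
}

#' Uniaxial Cauchy stress of the incompressible Mooney-Rivlin solid
#'
#' Closed-form uniaxial response under incompressible kinematics
#' (\eqn{\lambda, \lambda^{-1/2}, \lambda^{-1/2}}):
#' \deqn{\sigma(\lambda) = 2\left(\lambda^2 - \lambda^{-1}\right)
#'   \left(A + B/\lambda\right),}
#' zero at the undeformed state \eqn{\lambda = 1} and strictly increasing
#' over physiological stretches for the default constants.
#'
#' @param stretch axial stretch ratio(s) \eqn{\lambda > 0}.
#' @param params a [mooney_rivlin()] parameter set.
#' @return Cauchy stress in MPa, same length as `stretch`.
#' @export
mr_uniaxial_stress <- function(stretch, params = mooney_rivlin()) {
  stopifnot(inherits(params, "mooney_rivlin"))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("`stretch` must be positive", call. = FALSE)
  2 * (stretch^2 - 1 / stretch) * (params$A + params$B / stretch)
}

#' Regional displacement summary
#'
#' Maximum and mean displacement magnitude per named wall region at selected
#' time steps — the reduced summary of a wall-displacement field (the kind a
#' structural solve exports).
#'
#' @param disp a [field_series()] of displacements (m or mm; units pass
#'   through).
#' @param regions named list of logical masks or index vectors over the
#'   field's points.
#' @param time_indices time steps to summarise (default: all).
#' @return data frame with columns `region`, `time_s`, `max`, `mean`.
#' @export
displacement_summary <- function(disp, regions,
                                 time_indices = seq_along(disp$times)) {
  stopifnot(inherits(disp, "field_series"))
  if (!length(regions) || is.null(names(regions)))
    stop("`regions` must be a named list of point masks", call. = FALSE)
  n_pts <- nrow(disp$points)
  rows <- list()
  for (rn in names(regions)) {
    sel <- regions[[rn]]
    if (is.logical(sel)) sel <- which(sel)
    if (!length(sel) || any(sel < 1 | sel > n_pts))
      stop(sprintf("region '%s' is empty or out of range", rn), call. = FALSE)
    for (j in time_indices) {
      mag <- sqrt(rowSums(field_at(disp, j)[sel, , drop = FALSE]^2))
      rows[[length(rows) + 1]] <- data.frame(
        region = rn, time_s = disp$times[j],
        max = max(mag), mean = mean(mag))
    }
  }
  do.call(rbind, rows)
}
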