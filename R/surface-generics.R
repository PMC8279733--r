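# Generic interface every potential energy surface in the package
# implements: energy and analytic gradient at a flattened coordinate
# vector (bohr -> hartree, hartree/bohr), plus a batched energy used by
# the diffusion Monte Carlo driver.

#' Evaluate a surface at one point
#'
#' @param surface a surface object (`pip_surface`, `composite_surface`,
#'   any analytic surrogate, ...).
#' @param x flattened coordinate vector (bohr) of length
#'   [surface_dim()], or a `mol_geometry` for molecular surfaces.
#' @param ... passed to methods.
#' @return potential energy in hartree.
#' @export
surface_energy <- function(surface, x, ...) UseMethod("surface_energy")

#' Analytic gradient of a surface at one point
#'
#' @inheritParams surface_energy
#' @return gradient vector (hartree/bohr), same length as `x`.
#' @export
surface_gradient <- function(surface, x, ...) UseMethod("surface_gradient")

#' Evaluate a surface at many points
#'
#' @param surface a surface object.
#' @param X numeric matrix, one row per evaluation point.
#' @return numeric vector of energies (hartree).
#' @export
surface_energy_batch <- function(surface, X) UseMethod("surface_energy_batch")

#' @export
surface_energy_batch.default <- function(surface, X) {
  apply(X, 1, function(row) surface_energy(surface, row))
}

#' Coordinate dimension of a surface
#'
#' @param surface a surface object.
#' @return integer number of coordinates (3N for molecular surfaces).
#' @export
surface_dim <- function(surface) surface$dim

#' Compose a low-level surface with a correction surface
#'
#' The delta-machine-learning composite V_LL->CC = V_LL + dV_CC-LL:
#' energies and gradients are pointwise sums of the low-level surface and
#' the fitted correction.
#'
#' @param low low-level surface.
#' @param corr correction surface (same coordinate dimension).
#' @return object of class `c("composite_surface", "pes_surface")`.
#' @export
compose_surfaces <- function(low, corr) {
  if (!identical(surface_dim(low), surface_dim(corr))) {
    stop(sprintf("surface dimension mismatch: low %d vs correction %d",
                 surface_dim(low), surface_dim(corr)))
  }
  structure(list(low = low, corr = corr, dim = surface_dim(low)),
            class = c("composite_surface", "pes_surface"))
}

#' @export
surface_energy.composite_surface <- function(surface, x, ...) {
  surface_energy(surface$low, x) + surface_energy(surface$corr, x)
}

#' @export
surface_gradient.composite_surface <- function(surface, x, ...) {
  surface_gradient(surface$low, x) + surface_gradient(surface$corr, x)
}

#' @export
surface_energy_batch.composite_surface <- function(surface, X) {
  surface_energy_batch(surface$low, X) + surface_energy_batch(surface$corr, X)
}

#' @export
print.composite_surface <- function(x, ...) {
  cat(sprintf("<composite_surface> dim %d: low-level %s + correction %s\n",
              x$dim, class(x$low)[1], class(x$corr)[1]))
  invisible(x)
}

#' Fit a one-dimensional polynomial surface
#'
#' Least-squares polynomial in a single coordinate, solved by the same
#' SVD solver as [pip_fit()]. Used to fit correction surfaces for 1d
#' surrogate problems.
#'
#' @param q numeric vector of coordinates.
#' @param energy numeric vector of energies (hartree).
#' @param degree polynomial degree.
#' @param weights optional weights.
#' @return object of class `c("poly1d_surface", "pes_surface")` with
#'   `coeffs` (constant first) and `training_rms` (hartree).
#' @export
poly1d_fit <- function(q, energy, degree = 4, weights = NULL) {
  A <- outer(q, 0:degree, `^`)
  sol <- .lsq_svd(A, energy, weights)
  s <- poly1d_surface(sol$coefficients)
  s$training_rms <- sqrt(mean((A %*% sol$coefficients - energy)^2))
  s
}

#' One-dimensional polynomial surface
#'
#' @param coeffs polynomial coefficients, constant term first.
#' @return object of class `c("poly1d_surface", "pes_surface")`.
#' @export
poly1d_surface <- function(coeffs) {
  structure(list(coeffs = as.numeric(coeffs), dim = 1L),
            class = c("poly1d_surface", "pes_surface"))
}

#' @export
surface_energy.poly1d_surface <- function(surface, x, ...) {
  sum(surface$coeffs * x[1]^(seq_along(surface$coeffs) - 1))
}

#' @export
surface_gradient.poly1d_surface <- function(surface, x, ...) {
  p <- seq_along(surface$coeffs) - 1
  sum(surface$coeffs[-1] * p[-1] * x[1]^(p[-1] - 1))
}

#' @export
surface_energy_batch.poly1d_surface <- function(surface, X) {
  as.vector(outer(X[, 1], seq_along(surface$coeffs) - 1, `^`) %*% surface$coeffs)
}
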