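# One-dimensional tunneling: the minimum-energy path along the saddle
# point's imaginary-frequency normal mode (Q_im), barrier morphing by
# uniform energy scaling, and sinc-DVR eigenvalues of the resulting 1d
# double well (Colbert-Miller uniform-grid kinetic matrix).
#
# Paths are stored in the mass-scaled convention: the path coordinate q is
# in bohr*sqrt(m_e) and the DVR effective mass is 1, so isotope changes
# rescale q rather than the kinetic operator.

#' Construct a 1d path object
#'
#' @param q strictly increasing grid of mass-scaled displacements
#'   (bohr*sqrt(m_e)).
#' @param energy potential along the path (hartree), referenced so the
#'   well minimum is zero (`reference_energy` keeps the subtracted value).
#' @param effective_mass mass for DVR (electron masses); 1 in the
#'   mass-scaled convention.
#' @param morph_factor energy scale already applied (1 = unmorphed).
#' @param reference_energy absolute energy subtracted from the path.
#' @return object of class `path_1d`.
#' @export
path_1d <- function(q, energy, effective_mass = 1, morph_factor = 1,
                    reference_energy = 0) {
  q <- as.numeric(q); energy <- as.numeric(energy)
  if (length(q) != length(energy)) stop("q/energy length mismatch")
  if (any(!is.finite(q)) || any(!is.finite(energy))) stop("path values must be finite")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  structure(list(q = q, energy = energy, effective_mass = effective_mass,
                 morph_factor = morph_factor,
                 reference_energy = reference_energy),
            class = "path_1d")
}

#' @export
print.path_1d <- function(x, ...) {
  b <- tryCatch(path_barrier(x), error = function(e) NA_real_)
  cat(sprintf("<path_1d> %d points, q in [%.3g, %.3g]; barrier %.4g hartree (morph %.4g)\n",
              length(x$q), min(x$q), max(x$q), b, x$morph_factor))
  invisible(x)
}

#' Barrier height of a 1d path
#'
#' The maximum of the path between its two outermost local minima (the
#' wells), measured from the lower well. An error if the path has fewer
#' than two local minima or no barrier between them.
#'
#' @param path a [path_1d()].
#' @return barrier height in hartree, with attribute `q_top` (the grid
#'   position of the barrier top).
#' @export
path_barrier <- function(path) {
  e <- path$energy
  n <- length(e)
  is_min <- vapply(2:(n - 1), function(i) e[i] <= e[i - 1] && e[i] <= e[i + 1],
                   logical(1))
  mins <- which(is_min) + 1L
  if (length(mins) < 2) stop("path has no double-well structure (fewer than two local minima)")
  lo <- min(mins); hi <- max(mins)
  seg <- e[lo:hi]
  b <- max(seg) - min(e[c(lo, hi)])
  if (b <= 0) stop("path has no interior barrier")
  attr(b, "q_top") <- path$q[lo:hi][which.max(seg)]
  b
}

#' Sample a 1d surface onto a mass-scaled path
#'
#' Convenience for 1d model surfaces: evaluates `surface` on a symmetric
#' grid spanning both wells and stores the mass-scaled path (q multiplied
#' by sqrt(mass), effective mass 1). For a [double_well_1d()] the default
#' grid spans `span` times the minima positions.
#'
#' @param surface a 1d surface (e.g. [double_well_1d()]).
#' @param mass particle mass in electron masses (default: the surface's
#'   own `mass` if present, else 1).
#' @param q_max grid half-width in bohr (default `span` times the outer
#'   minimum for a double well).
#' @param n number of grid points.
#' @param span multiplier for the default half-width.
#' @return a [path_1d()] with energies referenced to the well minimum.
#' @export
path_from_surface_1d <- function(surface, mass = NULL, q_max = NULL, n = 201,
                                 span = 2.5) {
  if (is.null(mass)) mass <- surface$mass %||% 1
  if (is.null(q_max)) {
    if (!is.null(surface$known$minima)) q_max <- span * max(abs(surface$known$minima))
    else stop("q_max required for surfaces without known minima")
  }
  qc <- seq(-q_max, q_max, length.out = n)
  e <- surface_energy_batch(surface, matrix(qc, ncol = 1))
  path_1d(qc * sqrt(mass), e - min(e), effective_mass = 1,
          reference_energy = min(e))
}

#' Minimum-energy path along the imaginary-frequency mode
#'
#' Builds V(Q_im): starting from a first-order saddle point, displaces
#' along the imaginary-frequency normal mode by q in mass-weighted
#' coordinates and, at each fixed q, relaxes all remaining degrees of
#' freedom -- the displacement direction itself and any frozen coordinates
#' are excluded from the relaxation, and frozen coordinates are held at
#' their saddle-point values all along the path (the treatment used for
#' internal-rotor coordinates that rectilinear normal modes cannot
#' describe). Energies are referenced to the path minimum.
#'
#' @param surface a molecular surface.
#' @param sp a `stationary_point` of order 1 (from [optimize_saddle()]).
#' @param masses per-atom masses (electron masses).
#' @param q_values mass-scaled displacement grid (bohr*sqrt(m_e)); must
#'   span both wells and include 0.
#' @param frozen optional logical vector (length 3N) or integer atom
#'   indices: coordinates clamped at saddle values.
#' @param relax set `FALSE` to skip relaxation (rigid cut).
#' @param reltol relaxation convergence tolerance passed to the optimizer.
#' @return a [path_1d()] (effective mass 1).
#' @export
qim_path <- function(surface, sp, masses, q_values, frozen = NULL,
                     relax = TRUE, reltol = 1e-12) {
  x0 <- sp$x
  D <- length(x0)
  mdof <- .expand_masses(masses, D)
  sm <- sqrt(mdof)
  if (sp$order != 1) stop("sp must be a first-order saddle point")
  ha <- harmonic_analysis(surface, x0, masses, project = TRUE)
  if (ha$frequencies[1] >= 0) stop("no imaginary frequency at the saddle point")
  u <- ha$modes[, 1]
  fr <- rep(FALSE, D)
  if (!is.null(frozen)) {
    if (is.logical(frozen)) {
      if (length(frozen) != D) stop("logical frozen mask must have length 3N")
      fr <- frozen
    } else {
      fr[as.vector(vapply(as.integer(frozen), function(a) 3L * (a - 1L) + 1:3,
                          integer(3)))] <- TRUE
    }
  }
  u[fr] <- 0
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) stop("imaginary mode lies entirely in the frozen subspace")
  u <- u / nu
  # relaxation basis: unfrozen directions orthogonal to u (mass-weighted)
  free_idx <- which(!fr)
  B <- NULL
  if (relax && length(free_idx) > 1) {
    M <- diag(D)[, free_idx, drop = FALSE]
    M <- M - u %*% (t(u) %*% M)
    qrd <- qr(M)
    r <- abs(diag(qr.R(qrd)))
    B <- qr.Q(qrd)[, which(r > 1e-8 * max(r)), drop = FALSE]
  }
  y0 <- sm * x0
  energies <- numeric(length(q_values))
  ord <- order(abs(q_values))
  z_pos <- NULL; z_neg <- NULL
  for (k in ord) {
    q <- q_values[k]
    y_t <- y0 + q * u
    if (is.null(B)) {
      energies[k] <- surface_energy(surface, y_t / sm)
      next
    }
    z0 <- if (q >= 0) z_pos else z_neg
    if (is.null(z0)) z0 <- numeric(ncol(B))
    fn <- function(z) surface_energy(surface, (y_t + as.vector(B %*% z)) / sm)
    gr <- function(z) {
      g <- surface_gradient(surface, (y_t + as.vector(B %*% z)) / sm)
      as.vector(t(B) %*% (g / sm))
    }
    opt <- stats::optim(z0, fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = reltol))
    if (opt$convergence != 0 && opt$convergence != 1) {
      stop(sprintf("path relaxation failed at q = %.4g (optim code %d)",
                   q, opt$convergence))
    }
    energies[k] <- opt$value
    if (q >= 0) z_pos <- opt$par
    if (q <= 0) z_neg <- opt$par
  }
  ref <- min(energies)
  path_1d(q_values, energies - ref, effective_mass = 1,
          reference_energy = ref)
}

#' Morph a path to a target barrier height
#'
#' Uniform energy scaling: all path energies are multiplied by
#' s = target / current barrier, so the morphed barrier equals the target
#' exactly while well positions are preserved. The applied factor
#' accumulates in `morph_factor`.
#'
#' @param path a [path_1d()] with a well-defined interior barrier.
#' @param target_cm target barrier height in cm^-1.
#' @return the morphed [path_1d()].
#' @export
morph_path <- function(path, target_cm) {
  b <- as.numeric(path_barrier(path))
  s <- (target_cm / hartree_to_cm) / b
  path_1d(path$q, path$energy * s, effective_mass = path$effective_mass,
          morph_factor = path$morph_factor * s,
          reference_energy = path$reference_energy)
}

#' Rescale the particle mass of a mass-scaled path
#'
#' Isotope substitution on a stored path: multiplying the moving mass by
#' `factor` stretches the mass-scaled coordinate by sqrt(factor)
#' (e.g. `factor = 2` for H -> D).
#'
#' @param path a [path_1d()].
#' @param factor mass ratio m_new / m_old.
#' @return rescaled [path_1d()].
#' @export
path_rescale_mass <- function(path, factor) {
  if (factor <= 0) stop("mass factor must be positive")
  path_1d(path$q * sqrt(factor), path$energy,
          effective_mass = path$effective_mass,
          morph_factor = path$morph_factor,
          reference_energy = path$reference_energy)
}

# Colbert-Miller sinc-DVR Hamiltonian on a uniform grid
.sinc_dvr_hamiltonian <- function(grid, V, mass) {
  n <- length(grid)
  dx <- grid[2] - grid[1]
  i <- matrix(seq_len(n), n, n)
  dij <- i - t(i)
  T <- matrix(0, n, n)
  off <- dij != 0
  T[off] <- 2 * (-1)^(dij[off]) / dij[off]^2
  diag(T) <- pi^2 / 3
  T <- T / (2 * mass * dx^2)
  T + diag(V)
}

#' Sinc-DVR eigenvalues of a 1d path
#'
#' Interpolates the path with a natural cubic spline onto a uniform grid
#' and diagonalizes the sinc-DVR (Colbert-Miller) Hamiltonian. The grid is
#' refined by doubling until the two lowest eigenvalues change by less
#' than `tol_cm`; an error reports the last change if the cap is reached.
#'
#' @param path a [path_1d()].
#' @param n_points initial grid size (>= 64; default 513).
#' @param tol_cm convergence tolerance on E0 and E1 in cm^-1.
#' @param max_doublings refinement cap.
#' @param n_states number of eigenvalues to return.
#' @return object of class `dvr_solution`: `grid`, `eigenvalues`
#'   (hartree, ascending), `vectors` (grid eigenvectors for the returned
#'   states), `splitting_cm` (E1 - E0 in cm^-1), `n_points`.
#' @export
dvr_levels <- function(path, n_points = 513, tol_cm = 0.01,
                       max_doublings = 4, n_states = 4) {
  if (n_points < 64) stop("n_points must be >= 64")
  sf <- stats::splinefun(path$q, path$energy, method = "natural")
  n <- as.integer(n_points)
  prev <- NULL
  for (it in seq_len(max_doublings + 1L)) {
    grid <- seq(min(path$q), max(path$q), length.out = n)
    eg <- eigen(.sinc_dvr_hamiltonian(grid, sf(grid), path$effective_mass),
                symmetric = TRUE)
    ev <- rev(eg$values)[seq_len(n_states)]
    vecs <- eg$vectors[, rev(seq_len(n))[seq_len(n_states)], drop = FALSE]
    if (!is.null(prev)) {
      delta <- max(abs(ev[1:2] - prev[1:2])) * hartree_to_cm
      if (delta < tol_cm) {
        return(structure(list(grid = grid, eigenvalues = ev, vectors = vecs,
                              splitting_cm = (ev[2] - ev[1]) * hartree_to_cm,
                              n_points = n),
                         class = "dvr_solution"))
      }
      if (it == max_doublings + 1L) {
        stop(sprintf("DVR not converged after %d doublings: last E0/E1 change %.3g cm^-1",
                     max_doublings, delta))
      }
    }
    prev <- ev
    n <- 2L * n - 1L
  }
}

#' @export
print.dvr_solution <- function(x, ...) {
  cat(sprintf("<dvr_solution> %d grid points; E0 = %.8g, E1 = %.8g hartree; splitting %.4g cm^-1\n",
              x$n_points, x$eigenvalues[1], x$eigenvalues[2], x$splitting_cm))
  invisible(x)
}
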