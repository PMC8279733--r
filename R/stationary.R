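# Stationary-point location and harmonic analysis.
#
# Minima: BFGS followed by Newton polishing with eigenvalue clamping.
# First-order saddles: eigenvector-following Newton steps (the lowest
# Hessian mode is walked uphill, all others downhill), optionally in
# mass-weighted coordinates. Hessians come from central finite differences
# of the analytic gradient.

.max_norm <- function(g) max(abs(g))

#' Finite-difference Hessian of a surface
#'
#' Central differences of the analytic gradient, symmetrized.
#'
#' @param surface a surface object.
#' @param x coordinate vector (bohr).
#' @param step finite-difference step in bohr (default 5e-3).
#' @return symmetric D x D matrix (hartree/bohr^2).
#' @export
fd_hessian <- function(surface, x, step = 5e-3) {
  x <- coords_vector(x)
  D <- length(x)
  H <- matrix(0, D, D)
  for (k in seq_len(D)) {
    xp <- x; xp[k] <- xp[k] + step
    xm <- x; xm[k] <- xm[k] - step
    H[, k] <- (surface_gradient(surface, xp) - surface_gradient(surface, xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

# Hessian eigenvalue count below -tol, ignoring near-zero (external) modes
.hessian_order <- function(H, zero_tol = NULL) {
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(1, max(abs(lam)))
  sum(lam < -zero_tol)
}

.make_stationary_point <- function(surface, x, order, grad_norm, iterations) {
  structure(list(x = x, energy = surface_energy(surface, x), order = order,
                 grad_norm = grad_norm, iterations = iterations,
                 frequencies = NULL, modes = NULL),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("<stationary_point> order %d, E = %.10g hartree, |grad|_max = %.3g\n",
              x$order, x$energy, x$grad_norm))
  invisible(x)
}

#' Locate a minimum on a surface
#'
#' BFGS descent followed by Newton polishing (finite-difference Hessian,
#' eigenvalues clamped positive, near-zero external modes excluded from
#' the step) until the gradient max-norm drops below `tol`. A start whose
#' gradient already satisfies `tol` is returned immediately with zero
#' iterations.
#'
#' @param surface a surface object.
#' @param start starting coordinates (vector or `mol_geometry`).
#' @param tol gradient max-norm tolerance in hartree/bohr (default 1e-6).
#' @param max_iter Newton polishing iteration cap.
#' @return a `stationary_point` (fields `x`, `energy`, `order`,
#'   `grad_norm`, `iterations`).
#' @export
optimize_minimum <- function(surface, start, tol = 1e-6, max_iter = 100) {
  x <- coords_vector(start)
  g <- surface_gradient(surface, x)
  if (.max_norm(g) <= tol) {
    H <- fd_hessian(surface, x)
    return(.make_stationary_point(surface, x, .hessian_order(H), .max_norm(g), 0L))
  }
  opt <- stats::optim(x, fn = function(z) surface_energy(surface, z),
                      gr = function(z) surface_gradient(surface, z),
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  x <- opt$par
  it <- 0L
  repeat {
    g <- surface_gradient(surface, x)
    if (.max_norm(g) <= tol) break
    if (it >= max_iter) {
      stop(sprintf("minimum search did not converge: |grad|_max = %.3g after %d Newton iterations",
                   .max_norm(g), it))
    }
    H <- fd_hessian(surface, x)
    eg <- eigen(H, symmetric = TRUE)
    lam <- eg$values
    scale <- max(1e-6, max(abs(lam)))
    keep <- abs(lam) > 1e-9 * scale
    gq <- as.vector(t(eg$vectors) %*% g)
    step <- numeric(length(x))
    lam_eff <- pmax(abs(lam[keep]), 1e-8 * scale)
    step <- -eg$vectors[, keep, drop = FALSE] %*% (gq[keep] / lam_eff)
    if (.max_norm(step) > 0.5) step <- step * 0.5 / .max_norm(step)
    x <- x + as.vector(step)
    it <- it + 1L
  }
  H <- fd_hessian(surface, x)
  ord <- .hessian_order(H)
  if (ord != 0) warning(sprintf("converged point has %d negative Hessian mode(s); not a minimum", ord))
  .make_stationary_point(surface, x, ord, .max_norm(g), it)
}

#' Locate a first-order saddle point on a surface
#'
#' Eigenvector-following Newton iteration: at each step the
#' finite-difference Hessian is diagonalized (in mass-weighted coordinates
#' when `masses` is given), near-zero external modes are discarded, and
#' the step moves uphill along the lowest remaining mode and downhill
#' along all others. The start must lie near a first-order saddle; at
#' convergence the Hessian must have exactly one negative eigenvalue,
#' otherwise an error reports the signature.
#'
#' @inheritParams optimize_minimum
#' @param masses optional per-atom (or per-coordinate) masses in electron
#'   masses for mass-weighted stepping.
#' @return a `stationary_point` with `order = 1`.
#' @export
optimize_saddle <- function(surface, start, tol = 1e-6, masses = NULL,
                            max_iter = 200) {
  x <- coords_vector(start)
  D <- length(x)
  mdof <- rep(1, D)
  if (!is.null(masses)) {
    if (length(masses) * 3L == D) mdof <- rep(masses, each = 3L)
    else if (length(masses) == D) mdof <- masses
    else stop("masses length must match atoms or coordinates")
  }
  sm <- sqrt(mdof)
  it <- 0L
  repeat {
    g <- surface_gradient(surface, x)
    if (.max_norm(g) <= tol) break
    if (it >= max_iter) {
      stop(sprintf("saddle search did not converge: |grad|_max = %.3g after %d iterations",
                   .max_norm(g), it))
    }
    H <- fd_hessian(surface, x)
    Hw <- H / outer(sm, sm)
    gw <- g / sm
    eg <- eigen(Hw, symmetric = TRUE)
    lam <- eg$values
    scale <- max(1e-6, max(abs(lam)))
    keep <- which(abs(lam) > 1e-8 * scale)
    if (length(keep) == 0) stop("saddle search: Hessian numerically zero")
    low <- keep[which.min(lam[keep])]
    gq <- as.vector(t(eg$vectors) %*% gw)
    sq <- numeric(D)
    sq[keep] <- -gq[keep] / abs(lam[keep])
    sq[low] <- +gq[low] / abs(lam[low])
    step <- as.vector(eg$vectors %*% sq) / sm
    if (.max_norm(step) > 0.3) step <- step * 0.3 / .max_norm(step)
    x <- x + step
    it <- it + 1L
  }
  H <- fd_hessian(surface, x)
  Hw <- H / outer(sm, sm)
  lam <- eigen(Hw, symmetric = TRUE, only.values = TRUE)$values
  zt <- 1e-8 * max(1, max(abs(lam)))
  n_neg <- sum(lam < -zt); n_zero <- sum(abs(lam) <= zt)
  if (n_neg != 1) {
    stop(sprintf("converged to a stationary point of the wrong signature: %d negative, %d zero, %d positive modes",
                 n_neg, n_zero, length(lam) - n_neg - n_zero))
  }
  .make_stationary_point(surface, x, 1L, .max_norm(g), it)
}

# orthonormal basis of the translation/rotation space at a geometry,
# mass-weighted (Eckart-frame external modes)
.external_modes <- function(x, mdof) {
  D <- length(x)
  n <- D / 3L
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  masses <- mdof[seq(1, D, by = 3)]
  com <- colSums(cm * masses) / sum(masses)
  rel <- sweep(cm, 2, com)
  sm <- sqrt(mdof)
  vecs <- matrix(0, D, 6)
  for (k in 1:3) {                       # translations
    v <- numeric(D); v[seq(k, D, by = 3)] <- sqrt(masses)
    vecs[, k] <- v
  }
  ax <- diag(3)
  for (k in 1:3) {                       # rotations: sqrt(m) (r - com) x e_k
    cr <- t(apply(rel, 1, function(r) crossprod_vec3(r, ax[, k])))
    vecs[, 3 + k] <- as.vector(t(cr * sqrt(masses)))
  }
  qrd <- qr(vecs)
  rank <- sum(abs(diag(qr.R(qrd))) > 1e-8 * max(abs(diag(qr.R(qrd))), 1))
  qr.Q(qrd)[, seq_len(rank), drop = FALSE]
}

# 3-vector cross product (kept trivial and local)
crossprod_vec3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Harmonic normal-mode analysis at a stationary point
#'
#' Mass-weighted finite-difference Hessian (central differences, step
#' 5e-3 bohr); with `project = TRUE` the translational and rotational
#' external modes are projected out via the standard Eckart-frame
#' projector and the corresponding near-zero eigenvalues dropped from the
#' report. Frequencies are returned in cm^-1, sorted ascending, with
#' imaginary frequencies stored as negative numbers.
#'
#' @param surface a surface object.
#' @param x coordinates of a stationary point (gradient max-norm <= 1e-5
#'   expected, otherwise a warning is issued).
#' @param masses per-atom or per-coordinate masses (electron masses).
#' @param project project out translations/rotations (molecular surfaces);
#'   set `FALSE` for model surfaces whose coordinates are not Cartesian
#'   triples.
#' @param step Hessian finite-difference step (bohr).
#' @return object of class `harmonic_analysis`: `frequencies` (cm^-1),
#'   `modes` (mass-weighted normal-mode columns matching `frequencies`),
#'   `n_external` (number of projected modes).
#' @export
harmonic_analysis <- function(surface, x, masses, project = TRUE, step = 5e-3) {
  x <- coords_vector(x)
  D <- length(x)
  if (length(masses) * 3L == D && project) mdof <- rep(masses, each = 3L)
  else if (length(masses) == D) mdof <- masses
  else if (length(masses) * 3L == D) mdof <- rep(masses, each = 3L)
  else stop("masses length must match atoms or coordinates")
  g <- surface_gradient(surface, x)
  if (.max_norm(g) > 1e-5) {
    warning(sprintf("harmonic analysis at a non-stationary point: |grad|_max = %.3g", .max_norm(g)))
  }
  H <- fd_hessian(surface, x, step = step)
  sm <- sqrt(mdof)
  Hw <- H / outer(sm, sm)
  n_ext <- 0L
  if (project) {
    Q <- .external_modes(x, mdof)
    n_ext <- ncol(Q)
    P <- diag(D) - Q %*% t(Q)
    Hw <- P %*% Hw %*% P
    Hw <- (Hw + t(Hw)) / 2
  }
  eg <- eigen(Hw, symmetric = TRUE)
  lam <- eg$values
  freq <- sign(lam) * sqrt(abs(lam)) * hartree_to_cm
  if (n_ext > 0) {
    drop_idx <- order(abs(lam))[seq_len(n_ext)]
    keep <- setdiff(seq_along(lam), drop_idx)
  } else {
    keep <- seq_along(lam)
  }
  ord <- keep[order(freq[keep])]
  structure(list(frequencies = freq[ord],
                 modes = eg$vectors[, ord, drop = FALSE],
                 n_external = n_ext),
            class = "harmonic_analysis")
}

#' @export
print.harmonic_analysis <- function(x, ...) {
  fr <- x$frequencies
  lab <- ifelse(fr < 0, sprintf("%.1fi", abs(fr)), sprintf("%.1f", fr))
  cat(sprintf("<harmonic_analysis> %d modes (%d external projected):\n  %s cm^-1\n",
              length(fr), x$n_external, paste(lab, collapse = " ")))
  invisible(x)
}

#' Mean absolute error between two frequency lists
#'
#' Both lists are sorted ascending before differencing (imaginary entries,
#' stored as negative numbers, sort first and are matched to each other).
#'
#' @param a,b numeric frequency vectors of equal length (cm^-1).
#' @return mean absolute difference (cm^-1).
#' @export
freq_mae <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("frequency list length mismatch: %d vs %d", length(a), length(b)))
  }
  mean(abs(sort(a) - sort(b)))
}
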