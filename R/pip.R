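# Permutationally invariant polynomial (PIP) bases in Morse variables.
#
# A PIP basis function p_i is the sum of one orbit of monomials in the
# C(n,2) Morse pair variables x_ab = exp(-r_ab / lambda), the orbit being
# taken under the product symmetric group defined by a symmetry designation
# (like-atom block sizes, e.g. {1,2,5,7}). Orbits are enumerated by
# breadth-first closure under transposition generators acting on monomials;
# iterating over all group elements (|S2 x S5 x S7| = 1 209 600) would be
# infeasible at 15 atoms, so full-group iteration exists only as the
# small-case brute-force oracle pip_orbit_count_bruteforce().

# permutation of pair indices induced by an atom permutation
.induced_pair_perm <- function(n, atom_perm, pairs = pair_table(n)) {
  idx <- matrix(0L, n, n)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    idx[i, j] <- k; idx[j, i] <- k
  }
  vapply(seq_len(ncol(pairs)), function(k) {
    idx[atom_perm[pairs[1, k]], atom_perm[pairs[2, k]]]
  }, integer(1))
}

# adjacent transpositions within each like-atom block; these generate the
# full product symmetric group
.block_generators <- function(group_sizes) {
  n <- sum(group_sizes)
  gens <- list()
  off <- 0L
  for (s in group_sizes) {
    if (s >= 2) {
      for (t in seq_len(s - 1L)) {
        p <- seq_len(n)
        p[off + t] <- off + t + 1L
        p[off + t + 1L] <- off + t
        gens[[length(gens) + 1L]] <- p
      }
    }
    off <- off + s
  }
  gens
}

# monomials of total degree k over m variables, as columns of sorted
# (nondecreasing) variable-index multisets
.monomials_degree <- function(m, k) {
  if (k == 1) return(matrix(seq_len(m), nrow = 1))
  cmb <- utils::combn(m + k - 1L, k)
  cmb - (seq_len(k) - 1L)
}

# TRUE if dense exponent vector of v1 is lexicographically smaller than v2's
.dense_lex_less <- function(v1, v2, m) {
  e1 <- tabulate(v1, m)
  e2 <- tabulate(v2, m)
  d <- which(e1 != e2)
  if (length(d) == 0) return(FALSE)
  e1[d[1]] < e2[d[1]]
}

#' Enumerate a permutationally invariant polynomial basis
#'
#' Enumerates all monomial orbits of total degree 1..`max_degree` over the
#' C(n,2) Morse pair variables under the product symmetric group given by
#' `group_sizes` (the symmetry designation: like-atom block sizes, atoms
#' ordered block by block). Orbits are found by breadth-first closure under
#' the block transposition generators; the canonical representative of each
#' orbit is its lexicographically smallest dense exponent vector. The
#' constant term is not counted in `n_p`; it is carried as a separate
#' leading coefficient by [pip_surface()].
#'
#' @param group_sizes integer vector of like-atom block sizes, e.g.
#'   `c(1, 2, 5, 7)` for a 15-atom molecule with one unique atom and blocks
#'   of 2, 5 and 7 interchangeable atoms.
#' @param max_degree maximum total polynomial degree (>= 1).
#' @return an object of class `pip_basis` with fields `group_sizes`,
#'   `n_atoms`, `n_pairs`, `max_degree`, `orbits` (list; each orbit holds
#'   `monomials`, a list of sorted pair-index multisets, plus `rep` and
#'   `degree`) and `n_p` (orbit count).
#' @examples
#' pip_basis(c(2), 2)$n_p      # homonuclear diatomic: x, x^2
#' @export
pip_basis <- function(group_sizes, max_degree) {
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1)) stop("block sizes must be >= 1")
  if (max_degree < 1) stop("max_degree must be >= 1")
  n <- sum(group_sizes)
  if (n < 2) stop("symmetry designation must cover at least 2 atoms")
  m <- choose(n, 2)
  pairs <- pair_table(n)
  gens <- lapply(.block_generators(group_sizes), .induced_pair_perm,
                 n = n, pairs = pairs)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  orbits <- list()
  for (k in seq_len(max_degree)) {
    monos <- .monomials_degree(m, k)
    for (col in seq_len(ncol(monos))) {
      v <- monos[, col]
      key <- paste(v, collapse = ",")
      if (!is.null(seen[[key]])) next
      # breadth-first closure of v under the generators
      seen[[key]] <- TRUE
      queue <- list(v)
      members <- list()
      while (length(queue) > 0) {
        w <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        members[[length(members) + 1L]] <- w
        for (g in gens) {
          u <- sort.int(g[w])
          ku <- paste(u, collapse = ",")
          if (is.null(seen[[ku]])) {
            seen[[ku]] <- TRUE
            queue[[length(queue) + 1L]] <- u
          }
        }
      }
      rep_v <- members[[1]]
      for (w in members) if (.dense_lex_less(w, rep_v, m)) rep_v <- w
      orbits[[length(orbits) + 1L]] <- list(monomials = members,
                                            rep = rep_v, degree = k)
    }
  }
  structure(list(group_sizes = group_sizes, n_atoms = n, n_pairs = m,
                 max_degree = as.integer(max_degree), orbits = orbits,
                 n_p = length(orbits)),
            class = "pip_basis")
}

#' @export
print.pip_basis <- function(x, ...) {
  cat(sprintf(
    "<pip_basis> designation {%s}, %d atoms, %d pair variables, degree <= %d: n_p = %d orbits\n",
    paste(x$group_sizes, collapse = ","), x$n_atoms, x$n_pairs,
    x$max_degree, x$n_p))
  invisible(x)
}

# all permutations of 1..k (k small); used only by the brute-force oracle
.all_perms <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .all_perms(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Brute-force orbit count by full group enumeration
#'
#' Independent cross-check for [pip_basis()]: materializes every element of
#' the product symmetric group, applies each to every monomial and counts
#' distinct canonical images. Cost grows with the group order, so this is
#' only usable for small designations (<= ~7 atoms, low degree).
#'
#' @inheritParams pip_basis
#' @return integer orbit count (degrees 1..`max_degree`, constant excluded).
#' @export
pip_orbit_count_bruteforce <- function(group_sizes, max_degree) {
  group_sizes <- as.integer(group_sizes)
  n <- sum(group_sizes)
  m <- choose(n, 2)
  pairs <- pair_table(n)
  # full group: products of per-block permutations
  block_perms <- lapply(group_sizes, .all_perms)
  grid <- do.call(expand.grid, lapply(block_perms, seq_along))
  offs <- cumsum(c(0L, group_sizes))[seq_along(group_sizes)]
  perm_mat <- matrix(0L, nrow(grid), m)  # pair permutation per group element
  for (r in seq_len(nrow(grid))) {
    ap <- integer(n)
    for (b in seq_along(group_sizes)) {
      ap[offs[b] + seq_len(group_sizes[b])] <-
        offs[b] + block_perms[[b]][[grid[r, b]]]
    }
    perm_mat[r, ] <- .induced_pair_perm(n, ap, pairs)
  }
  base <- m + 1L
  canon <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  for (k in seq_len(max_degree)) {
    monos <- .monomials_degree(m, k)
    for (col in seq_len(ncol(monos))) {
      v <- monos[, col]
      img <- perm_mat[, v, drop = FALSE]          # |G| x k images
      img <- t(apply(img, 1, sort.int))           # row-sorted multisets
      if (k == 1) img <- matrix(img, ncol = 1)
      code <- as.vector(img %*% base^(seq_len(k) - 1))  # injective encode
      key <- sprintf("%d:%.0f", k, min(code))
      if (is.null(canon[[key]])) {
        canon[[key]] <- TRUE
        count <- count + 1L
      }
    }
  }
  count
}

#' Morse variables of a geometry
#'
#' Computes the vector of pair variables x_ab = exp(-r_ab / lambda) over
#' all atom pairs in the frozen lexicographic order, with r_ab the
#' internuclear distance in bohr.
#'
#' @param geom a `mol_geometry` or flattened coordinate vector (bohr).
#' @param lambda Morse range parameter in bohr (default 2).
#' @param n_atoms atom count when `geom` is a bare vector.
#' @return numeric vector of length C(n,2), every component in (0, 1].
#' @export
morse_variables <- function(geom, lambda = 2, n_atoms = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  x <- coords_vector(geom)
  if (!all(is.finite(x))) stop("coordinates must be finite")
  r <- pair_distances(x, n_atoms = if (is.null(n_atoms)) length(x) / 3 else n_atoms)
  if (any(r == 0)) warning("coincident atoms: some pair distances are zero (x = 1)")
  exp(-r / lambda)
}

# values of all basis polynomials p_i at Morse-variable vector x
.pip_polys <- function(basis, x) {
  vapply(basis$orbits, function(o) {
    s <- 0
    for (v in o$monomials) s <- s + prod(x[v])
    s
  }, numeric(1))
}

# derivative of every p_i with respect to every Morse variable:
# n_p x n_pairs matrix
.pip_polys_dx <- function(basis, x) {
  m <- basis$n_pairs
  out <- matrix(0, basis$n_p, m)
  for (i in seq_along(basis$orbits)) {
    for (v in basis$orbits[[i]]$monomials) {
      pm <- prod(x[v])
      rl <- rle(v)  # v is sorted: rle gives distinct indices + multiplicities
      out[i, rl$values] <- out[i, rl$values] + rl$lengths * pm / x[rl$values]
    }
  }
  out
}

#' Construct a PIP surface from a basis and coefficients
#'
#' @param basis a [pip_basis()].
#' @param coeffs numeric vector of length `n_p + 1`; the first entry is the
#'   constant term c0, followed by one coefficient per orbit.
#' @param lambda Morse range parameter in bohr.
#' @return object of class `c("pip_surface", "pes_surface")`.
#' @export
pip_surface <- function(basis, coeffs, lambda = 2) {
  if (!inherits(basis, "pip_basis")) stop("basis must be a pip_basis")
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != basis$n_p + 1L) {
    stop(sprintf("coeffs must have length n_p + 1 = %d, got %d",
                 basis$n_p + 1L, length(coeffs)))
  }
  structure(list(basis = basis, coeffs = coeffs, lambda = lambda,
                 dim = 3L * basis$n_atoms),
            class = c("pip_surface", "pes_surface"))
}

#' @export
print.pip_surface <- function(x, ...) {
  cat(sprintf("<pip_surface> %d atoms, n_p = %d (+ constant), lambda = %g bohr\n",
              x$basis$n_atoms, x$basis$n_p, x$lambda))
  invisible(x)
}

#' @export
surface_energy.pip_surface <- function(surface, x, ...) {
  x <- coords_vector(x)
  if (length(x) != surface$dim) {
    stop(sprintf("coordinate length %d does not match surface dimension %d",
                 length(x), surface$dim))
  }
  xm <- morse_variables(x, surface$lambda, n_atoms = surface$basis$n_atoms)
  surface$coeffs[1] + sum(surface$coeffs[-1] * .pip_polys(surface$basis, xm))
}

#' @export
surface_gradient.pip_surface <- function(surface, x, ...) {
  x <- coords_vector(x)
  n <- surface$basis$n_atoms
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  r <- pair_distances(x, n_atoms = n)
  if (any(r == 0)) stop("coincident atoms: gradient direction undefined")
  xm <- exp(-r / surface$lambda)
  dVdx <- as.vector(t(surface$coeffs[-1]) %*% .pip_polys_dx(surface$basis, xm))
  dVdr <- dVdx * (-xm / surface$lambda)
  grad <- matrix(0, n, 3)
  pairs <- pair_table(n)
  for (k in seq_along(r)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    u <- (cm[a, ] - cm[b, ]) / r[k]
    grad[a, ] <- grad[a, ] + dVdr[k] * u
    grad[b, ] <- grad[b, ] - dVdr[k] * u
  }
  as.vector(t(grad))
}

# design rows: basis polynomial values (energies) and Cartesian derivatives
# (gradients) for one geometry
.pip_design_energy_row <- function(basis, x, lambda) {
  xm <- morse_variables(x, lambda, n_atoms = basis$n_atoms)
  c(1, .pip_polys(basis, xm))
}

.pip_design_gradient_rows <- function(basis, x, lambda) {
  n <- basis$n_atoms
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  r <- pair_distances(x, n_atoms = n)
  xm <- exp(-r / lambda)
  dpdx <- .pip_polys_dx(basis, xm)            # n_p x n_pairs
  dpdr <- dpdx * matrix(-xm / lambda, basis$n_p, length(xm), byrow = TRUE)
  rows <- matrix(0, 3L * n, basis$n_p)
  pairs <- pair_table(n)
  for (k in seq_along(r)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    u <- (cm[a, ] - cm[b, ]) / r[k]
    ia <- 3L * (a - 1L) + 1:3
    ib <- 3L * (b - 1L) + 1:3
    rows[ia, ] <- rows[ia, ] + outer(u, dpdr[, k])
    rows[ib, ] <- rows[ib, ] - outer(u, dpdr[, k])
  }
  cbind(0, rows)
}

# SVD least squares with relative singular-value cutoff; shared by all
# linear fits in the package
.lsq_svd <- function(A, y, w = NULL, tol = 1e-10) {
  if (nrow(A) < ncol(A)) {
    stop(sprintf("underdetermined least-squares system: %d rows < %d columns",
                 nrow(A), ncol(A)))
  }
  if (!is.null(w)) {
    sw <- sqrt(w)
    A <- A * sw
    y <- y * sw
  }
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  rank <- sum(keep)
  if (rank < ncol(A)) {
    warning(sprintf("rank-deficient design matrix: rank %d < %d columns",
                    rank, ncol(A)))
  }
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  list(coefficients = as.vector(coef), rank = rank)
}

#' Fit a PIP surface to an energy (and optionally gradient) dataset
#'
#' Linear least squares for the coefficients of V = c0 + sum c_i p_i(x),
#' solved by singular value decomposition with a relative cutoff of 1e-10.
#' When `use_gradients = TRUE`, each stored gradient contributes its 3N
#' Cartesian components as additional rows, weighted by
#' `gradient_weight` (default 1/(3N), so one geometry's gradient carries
#' weight comparable to its energy).
#'
#' @param dataset an [energy_dataset()]; all records must share the atom
#'   count and ordering assumed by `basis`.
#' @param basis a [pip_basis()].
#' @param lambda Morse range parameter in bohr (default 2).
#' @param use_gradients include gradient rows for records that carry them.
#' @param weights optional per-record weights (default all 1).
#' @param gradient_weight weight multiplier for each gradient component row.
#' @param svd_tol relative singular-value cutoff.
#' @return object of class `pip_fit`: `surface` (a [pip_surface()]),
#'   `training_rms_cm` (RMS energy residual in cm^-1), `rank`,
#'   `n_energy_rows`, `n_gradient_rows`.
#' @export
pip_fit <- function(dataset, basis, lambda = 2, use_gradients = FALSE,
                    weights = NULL, gradient_weight = NULL, svd_tol = 1e-10) {
  recs <- dataset$records
  if (length(recs) == 0) stop("empty dataset")
  if (is.null(weights)) weights <- rep(1, length(recs))
  if (length(weights) != length(recs)) stop("weights/records length mismatch")
  D <- 3L * basis$n_atoms
  if (is.null(gradient_weight)) gradient_weight <- 1 / D

  rows <- list(); ys <- list(); ws <- list(); is_energy <- list()
  for (i in seq_along(recs)) {
    x <- coords_vector(recs[[i]]$geometry)
    rows[[length(rows) + 1L]] <- .pip_design_energy_row(basis, x, lambda)
    ys[[length(ys) + 1L]] <- recs[[i]]$energy
    ws[[length(ws) + 1L]] <- weights[i]
    is_energy[[length(is_energy) + 1L]] <- TRUE
    if (use_gradients && !is.null(recs[[i]]$gradient)) {
      g <- .pip_design_gradient_rows(basis, x, lambda)
      rows[[length(rows) + 1L]] <- g
      ys[[length(ys) + 1L]] <- as.numeric(recs[[i]]$gradient)
      ws[[length(ws) + 1L]] <- rep(weights[i] * gradient_weight, D)
      is_energy[[length(is_energy) + 1L]] <- rep(FALSE, D)
    }
  }
  A <- do.call(rbind, rows)
  y <- unlist(ys)
  w <- unlist(ws)
  ie <- unlist(is_energy)

  sol <- .lsq_svd(A, y, w, tol = svd_tol)
  surf <- pip_surface(basis, sol$coefficients, lambda)
  res_e <- (A %*% sol$coefficients - y)[ie]
  structure(list(surface = surf,
                 training_rms_cm = sqrt(mean(res_e^2)) * hartree_to_cm,
                 rank = sol$rank,
                 n_energy_rows = sum(ie),
                 n_gradient_rows = sum(!ie)),
            class = "pip_fit")
}

#' @export
print.pip_fit <- function(x, ...) {
  cat(sprintf("<pip_fit> %d energy rows, %d gradient rows; training RMS %.4g cm^-1 (rank %d)\n",
              x$n_energy_rows, x$n_gradient_rows, x$training_rms_cm, x$rank))
  invisible(x)
}
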