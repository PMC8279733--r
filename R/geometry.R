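# Molecular geometries: per-atom labels, masses (electron masses) and
# Cartesian coordinates (bohr). Coordinates flatten row-major per atom,
# c(x1, y1, z1, x2, ...), the convention used by every surface and gradient
# in the package.

# isotope-resolved masses for the light elements the surrogates use,
# in amu; "X" is a generic methyl-like pseudo-atom
.atomic_masses_amu <- c(
  H = 1.00782503, D = 2.01410178, C = 12.0, N = 14.00307401,
  O = 15.99491462, F = 18.99840316, S = 31.97207117, Cl = 34.96885268,
  X = 15.03475
)

#' Create a molecular geometry
#'
#' @param labels character vector of element symbols (one per atom).
#' @param coords numeric n x 3 matrix of Cartesian coordinates in bohr.
#' @param masses optional numeric vector of atomic masses in electron
#'   masses; when `NULL`, looked up from `labels` (isotope-averaged light
#'   elements plus the generic pseudo-atom `"X"`).
#' @return an object of class `mol_geometry` with fields `labels`,
#'   `masses` and `coords`.
#' @export
geometry <- function(labels, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 2) stop("a geometry needs at least 2 atoms")
  if (length(labels) != n) stop("labels/coords length mismatch")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(masses)) {
    amu <- .atomic_masses_amu[labels]
    if (anyNA(amu)) {
      stop("no mass table entry for label(s): ",
           paste(unique(labels[is.na(amu)]), collapse = ", "),
           "; supply masses explicitly")
    }
    masses <- unname(amu) * amu_to_me
  }
  if (length(masses) != n) stop("masses/coords length mismatch")
  if (!all(is.finite(masses) & masses > 0)) stop("masses must be positive and finite")
  structure(list(labels = as.character(labels), masses = as.numeric(masses),
                 coords = unname(coords)),
            class = "mol_geometry")
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat(sprintf("<mol_geometry> %d atoms: %s\n", nrow(x$coords),
              paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Flatten a geometry (or pass a numeric vector through)
#'
#' @param x a `mol_geometry` or a numeric coordinate vector.
#' @return numeric vector `c(x1, y1, z1, x2, ...)` in bohr.
#' @keywords internal
#' @export
coords_vector <- function(x) {
  if (inherits(x, "mol_geometry")) as.vector(t(x$coords)) else as.numeric(x)
}

#' Rebuild a geometry from a flattened coordinate vector
#'
#' @param geom template `mol_geometry` supplying labels and masses.
#' @param x flattened coordinate vector (bohr).
#' @export
with_coords <- function(geom, x) {
  geometry(geom$labels, matrix(x, ncol = 3, byrow = TRUE), geom$masses)
}

# pair ordering is frozen: lexicographic over (alpha, beta), alpha < beta
# (columns of utils::combn(n, 2)); stats::dist returns distances in exactly
# this order

#' Atom-pair index table
#'
#' Columns are the C(n,2) atom pairs in the package's frozen lexicographic
#' order (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n atom count.
#' @return 2 x C(n,2) integer matrix.
#' @export
pair_table <- function(n) utils::combn(n, 2)

#' All internuclear distances of a geometry
#'
#' @param geom a `mol_geometry` or flattened coordinate vector.
#' @param n_atoms atom count (required when `geom` is a bare vector).
#' @return numeric vector of C(n,2) distances in bohr, frozen pair order.
#' @export
pair_distances <- function(geom, n_atoms = NULL) {
  if (inherits(geom, "mol_geometry")) {
    cm <- geom$coords
  } else {
    x <- as.numeric(geom)
    if (is.null(n_atoms)) n_atoms <- length(x) / 3
    cm <- matrix(x, ncol = 3, byrow = TRUE)
  }
  as.vector(stats::dist(cm))
}

#' RMS difference of all internuclear distances between two geometries
#'
#' The structure metric used to compare optimized geometries: the
#' root-mean-square difference over all C(n,2) internuclear distances,
#' reported in angstroms. Invariant under rigid rotation and translation
#' of either geometry, symmetric in its arguments, and zero iff all
#' pairwise distances agree. For a 15-atom molecule this averages over
#' 105 pairs.
#'
#' @param a,b `mol_geometry` objects with the same atom count and order.
#' @return RMS distance difference in angstroms, with attribute `n_pairs`.
#' @export
structure_rms <- function(a, b) {
  da <- pair_distances(a)
  db <- pair_distances(b)
  if (length(da) != length(db)) stop("atom-count mismatch between geometries")
  out <- sqrt(mean((da - db)^2)) * bohr_to_angstrom
  attr(out, "n_pairs") <- length(da)
  out
}
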