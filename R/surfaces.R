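# Analytic surrogate surfaces with known stationary points, barriers and
# spectra. These stand in for the ab initio (MP2 / coupled-cluster)
# databases the correction scheme targets, so that every downstream stage
# -- fitting, composition, optimization, DMC, DVR -- is testable against
# closed-form or construction-time truths.

#' Separable mass-weighted harmonic surface
#'
#' V(x) = sum_i (1/2) m_i w_i^2 x_i^2, one coordinate per mode. The exact
#' zero-point energy sum(w_i)/2 (cm^-1) is stored in `known$zpe_cm`.
#'
#' @param freqs_cm positive harmonic frequencies in cm^-1, one per mode.
#' @param masses per-mode masses in electron masses (default all 1).
#' @return object of class `c("harmonic_surface", "pes_surface")`.
#' @export
harmonic_surface <- function(freqs_cm, masses = rep(1, length(freqs_cm))) {
  if (any(freqs_cm <= 0)) stop("frequencies must be positive")
  if (length(masses) != length(freqs_cm)) stop("masses/freqs length mismatch")
  omega <- freqs_cm / hartree_to_cm           # angular frequency, au
  structure(list(omega = omega, masses = masses, dim = length(omega),
                 known = list(zpe_cm = sum(freqs_cm) / 2,
                              freqs_cm = freqs_cm)),
            class = c("harmonic_surface", "pes_surface"))
}

#' @export
surface_energy.harmonic_surface <- function(surface, x, ...) {
  sum(0.5 * surface$masses * surface$omega^2 * x^2)
}

#' @export
surface_gradient.harmonic_surface <- function(surface, x, ...) {
  surface$masses * surface$omega^2 * x
}

#' @export
surface_energy_batch.harmonic_surface <- function(surface, X) {
  as.vector(X^2 %*% (0.5 * surface$masses * surface$omega^2))
}

#' One-dimensional symmetric quartic double well
#'
#' V(q) = a q^4 - b q^2 with a, b > 0: the 1d analog of a symmetric
#' H-transfer double well. The analytic barrier b^2/(4a) and minima at
#' +/- sqrt(b/(2a)) are stored in `known`.
#'
#' @param a quartic coefficient (hartree/bohr^4).
#' @param b quadratic coefficient (hartree/bohr^2).
#' @param mass particle mass in electron masses.
#' @return object of class `c("double_well_1d", "pes_surface")`.
#' @export
double_well_1d <- function(a, b, mass = 1) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  q0 <- sqrt(b / (2 * a))
  structure(list(a = a, b = b, mass = mass, dim = 1L,
                 known = list(barrier = b^2 / (4 * a),
                              barrier_cm = b^2 / (4 * a) * hartree_to_cm,
                              minima = c(-q0, q0),
                              well_energy = -b^2 / (4 * a))),
            class = c("double_well_1d", "pes_surface"))
}

#' @export
surface_energy.double_well_1d <- function(surface, x, ...) {
  surface$a * x[1]^4 - surface$b * x[1]^2
}

#' @export
surface_gradient.double_well_1d <- function(surface, x, ...) {
  4 * surface$a * x[1]^3 - 2 * surface$b * x[1]
}

#' @export
surface_energy_batch.double_well_1d <- function(surface, X) {
  q <- X[, 1]
  surface$a * q^4 - surface$b * q^2
}

#' Reference H-transfer double well
#'
#' The package's frozen 1d surrogate for symmetric hydrogen transfer:
#' a [double_well_1d()] with barrier 1200 cm^-1 and well frequency
#' ~1320 cm^-1 for a proton-like mass, chosen so that the ground-state
#' tunneling splitting (~47 cm^-1 for H, ~6 cm^-1 for D by sinc-DVR) sits
#' in the regime typical of strong intramolecular H bonds. `mass_factor`
#' rescales the moving mass (2 for deuterium).
#'
#' @param mass_factor mass multiplier relative to the proton mass.
#' @return a [double_well_1d()].
#' @export
transfer_double_well <- function(mass_factor = 1) {
  double_well_1d(a = 0.0124785, b = 0.01652,
                 mass = 1836.15267343 * mass_factor)
}

# Morse bond term and derivative
.morse_bond <- function(r, D, alpha, r_e) {
  e <- 1 - exp(-alpha * (r - r_e))
  D * e^2
}
.morse_bond_d <- function(r, D, alpha, r_e) {
  ex <- exp(-alpha * (r - r_e))
  2 * D * (1 - ex) * alpha * ex
}

#' Proton-transfer toy molecule (X-O-H-O-X chain)
#'
#' A 5-atom surrogate for symmetric H-atom transfer between two equivalent
#' acceptor oxygens, with symmetry designation {1, 2, 2} (atom order
#' H, O, O, X, X; X is a methyl-like pseudo-atom). The potential is a sum
#' of distance terms: Morse bonds from H to each O, harmonic O-O, O-X and
#' 1-3 X..O restraints, plus a symmetric coupling
#' -c (x_HO2 - x_HO3)^2 in the Morse variables x = exp(-r/lambda_c) of
#' the two H-O distances, whose strength `coupling` raises the transfer
#' barrier (it vanishes at the symmetric saddle and lifts the wells).
#' Because the coupling is a quadratic in Morse variables, the difference
#' between two toys with different couplings lies exactly in the span of
#' a degree-2 PIP correction basis with the same range parameter.
#' By construction the energy is invariant under the simultaneous O-swap +
#' X-swap permutation. The two equivalent minima and the H-transfer saddle
#' are located numerically at construction; if no double-well structure is
#' found, construction fails. `known` stores the minimum and saddle
#' geometries and the barrier (hartree and cm^-1).
#'
#' @param coupling barrier-raising coupling strength in hartree (may be
#'   negative, lowering the barrier). The default pair
#'   [proton_transfer_pair()] uses a "high-level" value and a reduced
#'   "low-level" value whose barrier is ~65% of the high-level one.
#' @param D,alpha,r_e Morse well depth (hartree), range (1/bohr) and
#'   equilibrium distance (bohr) for the H-O bonds.
#' @param k_oo,R0 O-O harmonic force constant and equilibrium distance.
#' @param k_x,L_x O-X bond force constant and equilibrium distance.
#' @param k_13,rho 1-3 X..O restraint force constant and equilibrium
#'   distance (keeps the chain bent and rigid).
#' @param lambda_c Morse range parameter of the coupling term (bohr);
#'   matches the default PIP fitting range.
#' @return object of class `c("proton_transfer_toy", "pes_surface")`.
#' @export
proton_transfer_toy <- function(coupling = 0.15, D = 0.18, alpha = 2.5,
                                r_e = 1.8, k_oo = 1.5, R0 = 4.45,
                                k_x = 0.25, L_x = 2.6, k_13 = 0.08,
                                rho = 6.0, lambda_c = 2) {
  masses <- unname(.atomic_masses_amu[c("H", "O", "O", "X", "X")]) * amu_to_me
  s <- structure(list(params = list(coupling = coupling, D = D, alpha = alpha,
                                    r_e = r_e, k_oo = k_oo, R0 = R0,
                                    k_x = k_x, L_x = L_x, k_13 = k_13,
                                    rho = rho, lambda_c = lambda_c),
                      labels = c("H", "O", "O", "X", "X"),
                      masses = masses, dim = 15L, known = NULL),
                 class = c("proton_transfer_toy", "pes_surface"))
  # reference frame: O-O along x, X atoms bent off-axis, inversion-symmetric
  half <- R0 / 2
  xoff <- L_x * cos(110 * pi / 180)
  yoff <- L_x * sin(110 * pi / 180)
  right_start <- rbind(c(half - r_e, 0, 0),          # H near O3
                       c(-half, 0, 0),                # O2
                       c(half, 0, 0),                 # O3
                       c(-half + xoff, yoff, 0),      # X4
                       c(half - xoff, -yoff, 0))      # X5
  center_start <- right_start
  center_start[1, ] <- c(0, 0, 0)
  min_right <- optimize_minimum(s, as.vector(t(right_start)), tol = 1e-8)
  sp <- optimize_saddle(s, as.vector(t(center_start)), tol = 1e-8,
                        masses = masses)
  # the mirror minimum is the inversion image (combined O/X swap + H flip)
  min_left_x <- -min_right$x
  barrier <- sp$energy - min_right$energy
  cmm <- matrix(min_right$x, ncol = 3, byrow = TRUE)
  asym <- abs(sqrt(sum((cmm[1, ] - cmm[2, ])^2)) -
              sqrt(sum((cmm[1, ] - cmm[3, ])^2)))
  if (barrier <= 0 || asym < 1e-2) {
    stop("proton_transfer_toy: no double-well structure detected at these parameters")
  }
  s$known <- list(barrier = barrier,
                  barrier_cm = barrier * hartree_to_cm,
                  minimum = min_right$x,
                  minimum_mirror = min_left_x,
                  minimum_energy = min_right$energy,
                  saddle = sp$x,
                  saddle_energy = sp$energy)
  s
}

#' @export
surface_energy.proton_transfer_toy <- function(surface, x, ...) {
  p <- surface$params
  x <- coords_vector(x)
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  d <- function(i, j) sqrt(sum((cm[i, ] - cm[j, ])^2))
  r12 <- d(1, 2); r13 <- d(1, 3)
  x12 <- exp(-r12 / p$lambda_c); x13 <- exp(-r13 / p$lambda_c)
  .morse_bond(r12, p$D, p$alpha, p$r_e) +
    .morse_bond(r13, p$D, p$alpha, p$r_e) +
    0.5 * p$k_oo * (d(2, 3) - p$R0)^2 +
    0.5 * p$k_x * ((d(2, 4) - p$L_x)^2 + (d(3, 5) - p$L_x)^2) +
    0.5 * p$k_13 * ((d(3, 4) - p$rho)^2 + (d(2, 5) - p$rho)^2) -
    p$coupling * (x12 - x13)^2
}

#' @export
surface_gradient.proton_transfer_toy <- function(surface, x, ...) {
  p <- surface$params
  x <- coords_vector(x)
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  grad <- matrix(0, 5, 3)
  dist_ij <- function(i, j) sqrt(sum((cm[i, ] - cm[j, ])^2))
  add_pair <- function(i, j, dVdr) {
    r <- dist_ij(i, j)
    u <- (cm[i, ] - cm[j, ]) / r
    grad[i, ] <<- grad[i, ] + dVdr * u
    grad[j, ] <<- grad[j, ] - dVdr * u
  }
  r12 <- dist_ij(1, 2); r13 <- dist_ij(1, 3)
  x12 <- exp(-r12 / p$lambda_c); x13 <- exp(-r13 / p$lambda_c)
  # d/dr of -c (x12 - x13)^2 with dx/dr = -x/lambda
  dc12 <- 2 * p$coupling * (x12 - x13) * x12 / p$lambda_c
  dc13 <- -2 * p$coupling * (x12 - x13) * x13 / p$lambda_c
  add_pair(1, 2, .morse_bond_d(r12, p$D, p$alpha, p$r_e) + dc12)
  add_pair(1, 3, .morse_bond_d(r13, p$D, p$alpha, p$r_e) + dc13)
  add_pair(2, 3, p$k_oo * (dist_ij(2, 3) - p$R0))
  add_pair(2, 4, p$k_x * (dist_ij(2, 4) - p$L_x))
  add_pair(3, 5, p$k_x * (dist_ij(3, 5) - p$L_x))
  add_pair(3, 4, p$k_13 * (dist_ij(3, 4) - p$rho))
  add_pair(2, 5, p$k_13 * (dist_ij(2, 5) - p$rho))
  as.vector(t(grad))
}

#' @export
print.proton_transfer_toy <- function(x, ...) {
  cat(sprintf("<proton_transfer_toy> coupling %.4g hartree; barrier %.1f cm^-1\n",
              x$params$coupling, x$known$barrier_cm))
  invisible(x)
}

#' Low-level / high-level surrogate surface pair
#'
#' Two [proton_transfer_toy()] surfaces differing only in the coupling
#' strength, emulating a lower level of electronic-structure theory that
#' underestimates the H-transfer barrier (the low-level barrier is roughly
#' 65% of the high-level one, mirroring the typical MP2-vs-coupled-cluster
#' mismatch). The difference potential depends only on the two H-O
#' distances, is smooth and small relative to either full surface, and is
#' exactly invariant under the full {1,2,2} permutation group.
#'
#' @param coupling_high,coupling_low coupling strengths (hartree) of the
#'   high- and low-level variants.
#' @return list with elements `low` and `high`.
#' @export
proton_transfer_pair <- function(coupling_high = 0.15, coupling_low = -0.15) {
  list(low = proton_transfer_toy(coupling = coupling_low),
       high = proton_transfer_toy(coupling = coupling_high))
}

#' Geometry object for the toy molecule at given coordinates
#'
#' @param toy a [proton_transfer_toy()].
#' @param x flattened coordinates (default: its known minimum).
#' @export
toy_geometry <- function(toy, x = toy$known$minimum) {
  geometry(toy$labels, matrix(x, ncol = 3, byrow = TRUE), toy$masses)
}

#' Sample randomly displaced geometries around a point
#'
#' Every coordinate is displaced by an independent uniform random number
#' in +/- `del` (bohr), the scheme used to build surrogate databases
#' around stationary points.
#'
#' @param x center coordinates (flattened, bohr).
#' @param n number of samples.
#' @param del half-width of the uniform displacement (bohr).
#' @return n x length(x) matrix of coordinates.
#' @export
sample_displaced <- function(x, n, del) {
  x <- coords_vector(x)
  matrix(rep(x, each = n), nrow = n) +
    matrix(stats::runif(n * length(x), -del, del), nrow = n)
}

#' Generate paired low-level / high-level surrogate datasets
#'
#' Samples geometries uniformly displaced around the high-level minimum,
#' its mirror and the saddle point of a [proton_transfer_pair()], and
#' evaluates both surfaces, emulating a large low-level database and a
#' small high-level one spanning the same configurations. Energies are
#' absolute surface values (hartree); both datasets carry the high-level
#' minimum as reference geometry.
#'
#' @param pair a [proton_transfer_pair()].
#' @param n_low,n_high dataset sizes.
#' @param del uniform displacement half-width in bohr (default 0.25).
#' @param seed RNG seed (default 0).
#' @return list with `low` and `high` [energy_dataset()]s.
#' @export
surrogate_datasets <- function(pair = proton_transfer_pair(), n_low = 1500,
                               n_high = 300, del = 0.25, seed = 0) {
  set.seed(seed)
  centers <- rbind(pair$high$known$minimum,
                   pair$high$known$minimum_mirror,
                   pair$high$known$saddle)
  draw <- function(n) {
    per <- diff(round(seq(0, n, length.out = 4)))
    do.call(rbind, lapply(1:3, function(i) sample_displaced(centers[i, ], per[i], del)))
  }
  Xl <- draw(n_low)
  Xh <- draw(n_high)
  mk <- function(X, surf, level) {
    recs <- lapply(seq_len(nrow(X)), function(i) {
      list(geometry = geometry(pair$high$labels,
                               matrix(X[i, ], ncol = 3, byrow = TRUE),
                               pair$high$masses),
           energy = surface_energy(surf, X[i, ]),
           gradient = NULL, level = level)
    })
    energy_dataset(recs,
                   reference = list(geometry = toy_geometry(pair$high),
                                    energy = surface_energy(surf, pair$high$known$minimum)))
  }
  list(low = mk(Xl, pair$low, "low"), high = mk(Xh, pair$high, "high"))
}
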