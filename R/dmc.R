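# Diffusion Monte Carlo: the simple unbiased branching algorithm for
# ground-state energies, plus a fixed-node variant for the H-transfer
# excited state (walkers that cross the nodal surface are removed, with an
# optional Gaussian-bridge recrossing correction).
#
# One step: each walker is displaced by a Gaussian of variance dtau/m per
# degree of freedom; walkers with potential E_i below the reference energy
# E_r give birth with probability exp(-(E_i - E_r) dtau) - 1 (integer part
# forced, fraction sampled, capped at max_birth extra copies), walkers
# above E_r die with probability 1 - exp(-(E_i - E_r) dtau); then
# E_r <- <V> - alpha (N - N0)/N0. The production-time average of E_r
# estimates the zero-point (or fixed-node excited-state) energy.

#' Diffusion Monte Carlo run parameters
#'
#' @param n_walkers initial walker population N(0).
#' @param n_equil equilibration steps (discarded from the energy average).
#' @param n_prop production steps.
#' @param dtau imaginary-time step in au.
#' @param alpha population-control strength; default 1/`dtau`.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   traces.
#' @param max_birth cap on extra offspring per walker per step.
#' @return object of class `dmc_params`.
#' @export
dmc_params <- function(n_walkers = 2000, n_equil = 500, n_prop = 5000,
                       dtau = 5, alpha = NULL, seed = 1, max_birth = 3) {
  if (n_walkers < 1 || n_equil < 1 || n_prop < 1) stop("counts must be >= 1")
  if (dtau <= 0) stop("dtau must be positive")
  if (is.null(alpha)) alpha <- 1 / dtau
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(n_walkers = as.integer(n_walkers), n_equil = as.integer(n_equil),
                 n_prop = as.integer(n_prop), dtau = dtau, alpha = alpha,
                 seed = as.integer(seed), max_birth = as.integer(max_birth)),
            class = "dmc_params")
}

#' Nodal surface for fixed-node DMC
#'
#' @param fun function taking a walker-position matrix (one row per
#'   walker) and returning a signed value per walker; the zero set is the
#'   node. For coordinate-like node functions the value doubles as the
#'   signed distance used by the recrossing correction.
#' @param mass effective mass (electron masses) of the node-normal
#'   direction, used by the recrossing correction.
#' @return object of class `dmc_node`.
#' @export
dmc_node <- function(fun, mass = 1) {
  structure(list(fun = fun, mass = mass), class = "dmc_node")
}

#' Node at zero of one coordinate
#'
#' @param dim coordinate index.
#' @param mass mass of that degree of freedom (electron masses).
#' @export
coordinate_node <- function(dim, mass = 1) {
  dmc_node(function(X) X[, dim], mass = mass)
}

#' Node where two atom-atom distances are equal
#'
#' The fixed-node ansatz for symmetric H transfer: the node is
#' r(H, O_a) = r(H, O_b); the signed value is their difference. The
#' effective node-direction mass is the reduced mass of the two (equal)
#' distance coordinates.
#'
#' @param i_h,i_a,i_b atom indices of the transferring H and the two
#'   equivalent acceptors.
#' @param masses per-atom masses (electron masses).
#' @export
distance_difference_node <- function(i_h, i_a, i_b, masses) {
  mu <- masses[i_h] * masses[i_a] / (masses[i_h] + masses[i_a])
  fun <- function(X) {
    ch <- X[, 3 * (i_h - 1) + 1:3, drop = FALSE]
    ca <- X[, 3 * (i_a - 1) + 1:3, drop = FALSE]
    cb <- X[, 3 * (i_b - 1) + 1:3, drop = FALSE]
    sqrt(rowSums((ch - ca)^2)) - sqrt(rowSums((ch - cb)^2))
  }
  dmc_node(fun, mass = mu)
}

.expand_masses <- function(masses, D) {
  if (length(masses) == D) return(as.numeric(masses))
  if (length(masses) * 3L == D) return(rep(as.numeric(masses), each = 3L))
  stop("masses length must match atoms or coordinates")
}

.run_dmc <- function(surface, masses, params, start, node = NULL,
                     recross = FALSE) {
  D <- surface_dim(surface)
  mdof <- .expand_masses(masses, D)
  set.seed(params$seed)
  N0 <- params$n_walkers
  X <- matrix(rep(coords_vector(start), each = N0), nrow = N0)
  side <- NULL
  if (!is.null(node)) {
    s0 <- node$fun(X)
    if (any(s0 == 0) || length(unique(sign(s0))) != 1) {
      stop("initial walkers must lie strictly on one side of the node")
    }
    side <- sign(s0[1])
  }
  sigma <- sqrt(params$dtau / mdof)
  nsteps <- params$n_equil + params$n_prop
  E_r <- mean(surface_energy_batch(surface, X))
  e_r_tr <- numeric(nsteps)
  v_tr <- numeric(nsteps)
  n_tr <- integer(nsteps)
  for (step in seq_len(nsteps)) {
    N <- nrow(X)
    if (!is.null(node) && recross) s_old <- node$fun(X)
    Xn <- X + matrix(stats::rnorm(N * D), N, D) * rep(sigma, each = N)
    alive <- rep(TRUE, N)
    if (!is.null(node)) {
      s_new <- node$fun(Xn)
      alive <- sign(s_new) == side
      if (recross) {
        # Gaussian-bridge probability that the free path crossed and returned
        p_rec <- exp(-2 * abs(s_old) * abs(s_new) * node$mass / params$dtau)
        alive <- alive & (stats::runif(N) >= p_rec)
      }
    }
    Xn <- Xn[alive, , drop = FALSE]
    if (nrow(Xn) == 0) {
      stop("walker population went extinct; increase n_walkers or reduce dtau")
    }
    V <- surface_energy_batch(surface, Xn)
    w <- exp(-(V - E_r) * params$dtau)
    # very deep potential holes would overflow the birth weight; the cap on
    # offspring makes anything beyond max_birth + 1 equivalent anyway
    w[!is.finite(w) | w > params$max_birth + 2] <- params$max_birth + 2
    u <- stats::runif(length(V))
    nb <- floor(w - 1)
    copies <- ifelse(w >= 1,
                     1L + pmin(nb + (u < (w - 1 - nb)), params$max_birth),
                     as.integer(u < w))
    X <- Xn[rep(seq_along(copies), copies), , drop = FALSE]
    Nn <- nrow(X)
    if (Nn == 0) {
      stop("walker population went extinct; increase n_walkers or reduce dtau")
    }
    if (Nn > 50L * N0) {
      stop("walker population exploded beyond 50 x N(0); reduce dtau or check the surface")
    }
    v_mean <- mean(rep(V, copies))
    E_r <- v_mean - params$alpha * (Nn - N0) / N0
    e_r_tr[step] <- E_r
    v_tr[step] <- v_mean
    n_tr[step] <- Nn
  }
  prod_idx <- (params$n_equil + 1L):nsteps
  e_prod <- e_r_tr[prod_idx]
  nb <- 50L
  blocks <- split(e_prod, cut(seq_along(e_prod), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  structure(list(energy = mean(e_prod),
                 stderr = stats::sd(bm) / sqrt(length(bm)),
                 e_r = e_r_tr, mean_v = v_tr, n_walkers = n_tr,
                 positions = X, params = params,
                 fixed_node = !is.null(node)),
            class = "dmc_trace")
}

#' @export
print.dmc_trace <- function(x, ...) {
  cat(sprintf("<dmc_trace> %s: E = %.8g +/- %.2g hartree (%.1f +/- %.1f cm^-1), final N = %d\n",
              if (x$fixed_node) "fixed-node" else "ground",
              x$energy, x$stderr, x$energy * hartree_to_cm,
              x$stderr * hartree_to_cm, utils::tail(x$n_walkers, 1)))
  invisible(x)
}

#' Unbiased ground-state diffusion Monte Carlo
#'
#' @param surface a surface object (batched evaluation is used).
#' @param masses per-atom or per-coordinate masses (electron masses).
#' @param params a [dmc_params()].
#' @param start starting coordinates for all walkers.
#' @return a `dmc_trace`: `energy` (production-time average of the
#'   reference energy, hartree), `stderr` (block standard error), the
#'   per-step series `e_r`, `mean_v`, `n_walkers`, and the final walker
#'   `positions`.
#' @export
dmc_ground <- function(surface, masses, params, start) {
  .run_dmc(surface, masses, params, start)
}

#' Fixed-node diffusion Monte Carlo for an excited state
#'
#' As [dmc_ground()], but any walker whose node sign changes during a move
#' is removed; with `recross = TRUE` a surviving walker is additionally
#' removed with the Gaussian-bridge probability
#' exp(-2 d d' m / dtau), where d, d' are the node distances before and
#' after the move and m the node-direction effective mass. All initial
#' walkers must lie strictly on one side of the node. The resulting energy
#' is a variational upper bound to the excited state selected by the node.
#'
#' @inheritParams dmc_ground
#' @param node a [dmc_node()].
#' @param recross apply the recrossing correction (default `TRUE`).
#' @export
dmc_fixed_node <- function(surface, masses, node, params, start,
                           recross = TRUE) {
  .run_dmc(surface, masses, params, start, node = node, recross = recross)
}

#' Tunneling splitting from repeated DMC runs
#'
#' Combines independent ground-state and fixed-node runs:
#' splitting = mean(excited) - mean(ground), with uncertainty the
#' root-sum-square of the two run-to-run standard deviations.
#'
#' @param ground_runs,excited_runs lists of `dmc_trace` objects (energies
#'   converted to cm^-1) or plain numeric energy vectors (used as given);
#'   at least 2 runs per state.
#' @return list with `splitting`, `uncertainty`, `mean_ground`,
#'   `mean_excited`, `sd_ground`, `sd_excited` (cm^-1 for traces).
#' @export
dmc_splitting <- function(ground_runs, excited_runs) {
  as_vec <- function(runs) {
    if (is.numeric(runs)) return(runs)
    vapply(runs, function(r) {
      if (inherits(r, "dmc_trace")) r$energy * hartree_to_cm else as.numeric(r)
    }, numeric(1))
  }
  g <- as_vec(ground_runs)
  e <- as_vec(excited_runs)
  if (length(g) < 2 || length(e) < 2) {
    stop("at least 2 runs per state are required")
  }
  list(splitting = mean(e) - mean(g),
       uncertainty = sqrt(stats::sd(g)^2 + stats::sd(e)^2),
       mean_ground = mean(g), mean_excited = mean(e),
       sd_ground = stats::sd(g), sd_excited = stats::sd(e))
}

#' Histogram of walker positions
#'
#' Bins the final walker ensemble along one coordinate (or a 2d projection
#' onto two coordinates); counts sum to the number of walkers.
#'
#' @param x a `dmc_trace` or walker-position matrix.
#' @param dims one or two coordinate indices.
#' @param breaks number of bins per dimension.
#' @return for 1d, a list with `mids`, `counts`, `density`; for 2d a list
#'   with `xmids`, `ymids` and a count matrix `counts`.
#' @export
walker_histogram <- function(x, dims = 1, breaks = 50) {
  X <- if (inherits(x, "dmc_trace")) x$positions else as.matrix(x)
  if (length(dims) == 1) {
    v <- X[, dims]
    if (diff(range(v)) == 0) {
      return(list(mids = v[1], counts = nrow(X), density = NA_real_))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(mids = h$mids, counts = h$counts, density = h$density)
  } else if (length(dims) == 2) {
    bx <- seq(min(X[, dims[1]]), max(X[, dims[1]]), length.out = breaks + 1)
    by <- seq(min(X[, dims[2]]), max(X[, dims[2]]), length.out = breaks + 1)
    ix <- pmin(findInterval(X[, dims[1]], bx, rightmost.closed = TRUE), breaks)
    iy <- pmin(findInterval(X[, dims[2]], by, rightmost.closed = TRUE), breaks)
    counts <- matrix(0L, breaks, breaks)
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
    list(xmids = (bx[-1] + bx[-length(bx)]) / 2,
         ymids = (by[-1] + by[-length(by)]) / 2, counts = counts)
  } else {
    stop("dims must have length 1 or 2")
  }
}
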