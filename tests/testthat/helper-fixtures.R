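# Shared fixtures, memoized so expensive constructions run once per suite.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

toy_pair <- function() memo("toy_pair", proton_transfer_pair)

toy_high <- function() toy_pair()$high

toy_datasets <- function() {
  memo("toy_datasets", function() {
    surrogate_datasets(toy_pair(), n_low = 200, n_high = 240, del = 0.25,
                       seed = 1)
  })
}

# independent normal-equation least-squares oracle
normal_eq_fit <- function(A, y) {
  solve(t(A) %*% A, t(A) %*% y)
}

# independent 1d Schroedinger oracle: central-difference Hamiltonian on a
# dense grid, Richardson-extrapolated in the grid spacing (O(h^4))
fd_schrodinger_levels <- function(Vfun, mass, L, n_base = 1201, n_states = 2) {
  one <- function(N) {
    x <- seq(-L, L, length.out = N)
    h <- x[2] - x[1]
    V <- Vfun(x)
    H <- diag(1 / (mass * h^2) + V)
    H[cbind(1:(N - 1), 2:N)] <- -1 / (2 * mass * h^2)
    H[cbind(2:N, 1:(N - 1))] <- -1 / (2 * mass * h^2)
    rev(eigen(H, symmetric = TRUE, only.values = TRUE)$values)[seq_len(n_states)]
  }
  e1 <- one(n_base)
  e2 <- one(2L * n_base - 1L)
  (4 * e2 - e1) / 3
}

# all like-atom block permutations (as atom index vectors) for a designation
block_permutations <- function(group_sizes) {
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  offs <- cumsum(c(0L, group_sizes))
  per_block <- lapply(seq_along(group_sizes), function(b) {
    perms_of(offs[b] + seq_len(group_sizes[b]))
  })
  grid <- do.call(expand.grid, lapply(per_block, seq_along))
  lapply(seq_len(nrow(grid)), function(r) {
    unlist(lapply(seq_along(per_block), function(b) per_block[[b]][[grid[r, b]]]))
  })
}

# integer partitions of n (descending parts), used to enumerate symmetry
# designations with a given atom count
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq(min(n, max_part), 1)) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

random_toy_geometry <- function(scale = 0.3) {
  toy_high()$known$minimum + stats::runif(15, -scale, scale)
}
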