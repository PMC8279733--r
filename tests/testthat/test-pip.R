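test_that("morse variables have the closed-form values and range", {
  g2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(morse_variables(g2, lambda = 2), exp(-1))
  expect_warning(x0 <- morse_variables(c(0, 0, 0, 0, 0, 0)), "coincident")
  expect_equal(x0, 1)
  set.seed(4)
  x <- morse_variables(random_toy_geometry())
  expect_true(all(x > 0 & x <= 1))
})

test_that("like-atom relabeling permutes the morse variables as a multiset", {
  set.seed(5)
  x <- random_toy_geometry()
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  for (p in block_permutations(c(1, 2, 2))) {
    xp <- as.vector(t(cm[p, ]))
    expect_equal(sort(morse_variables(x)), sort(morse_variables(xp)),
                 tolerance = 1e-14)
  }
})

test_that("small bases have the expected orbit structure", {
  b1 <- pip_basis(c(2), 2)            # homonuclear diatomic: x, x^2
  expect_identical(b1$n_p, 2L)
  expect_identical(vapply(b1$orbits, function(o) o$degree, integer(1)), c(1L, 2L))
  b3 <- pip_basis(c(3), 2)            # A3: one linear, squares, mixed products
  expect_identical(b3$n_p, 3L)
  expect_identical(sort(vapply(b3$orbits, function(o) length(o$monomials), integer(1))),
                   c(3L, 3L, 3L))
  expect_error(pip_basis(c(2), 0), "max_degree")
  expect_error(pip_basis(c(0, 2), 1), "block sizes")
})

test_that("BFS orbit enumeration matches the full-group brute force", {
  for (gs in list(c(1, 1, 2), c(2, 2), c(4), c(1, 3))) {
    for (deg in 1:3) {
      expect_identical(pip_basis(gs, deg)$n_p,
                       pip_orbit_count_bruteforce(gs, deg),
                       info = paste0("{", paste(gs, collapse = ","), "} deg ", deg))
    }
  }
})

test_that("orbit sizes partition the full monomial set", {
  for (gs in list(c(1, 2, 2), c(3, 3), c(1, 1, 3))) {
    n <- sum(gs); m <- choose(n, 2)
    for (deg in 1:2) {
      b <- pip_basis(gs, deg)
      total <- sum(vapply(b$orbits, function(o) length(o$monomials), integer(1)))
      expect_identical(total, sum(vapply(1:deg, function(k) choose(m + k - 1, k), numeric(1))) |> as.integer())
    }
  }
})

test_that("PIP surfaces are permutationally invariant", {
  set.seed(6)
  basis <- pip_basis(c(1, 2, 2), 2)
  surf <- pip_surface(basis, stats::rnorm(basis$n_p + 1, sd = 0.05))
  perms <- block_permutations(c(1, 2, 2))
  for (i in 1:250) {
    x <- random_toy_geometry(scale = 0.5)
    cm <- matrix(x, ncol = 3, byrow = TRUE)
    v <- surface_energy(surf, x)
    p <- perms[[sample.int(length(perms), 1)]]
    vp <- surface_energy(surf, as.vector(t(cm[p, ])))
    expect_lt(abs(vp - v), 1e-12 * max(1, abs(v)))
  }
})

test_that("evaluation has the closed-form diatomic value and zero case", {
  basis <- pip_basis(c(2), 1)
  zero <- pip_surface(basis, c(0, 0))
  expect_equal(surface_energy(zero, c(0, 0, 0, 2, 0, 0)), 0)
  one <- pip_surface(basis, c(0.3, 1))
  expect_equal(surface_energy(one, c(0, 0, 0, 2, 0, 0)), 0.3 + exp(-1))
  expect_error(surface_energy(one, rep(0, 9)), "dimension")
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  basis <- pip_basis(c(1, 2, 2), 2)
  surf <- pip_surface(basis, stats::rnorm(basis$n_p + 1, sd = 0.05))
  h <- 1e-4
  for (i in 1:20) {
    x <- random_toy_geometry(scale = 0.4)
    g <- surface_gradient(surf, x)
    gfd <- vapply(seq_along(x), function(k) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      (surface_energy(surf, xp) - surface_energy(surf, xm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gfd)) / max(1e-10, max(abs(g))), 1e-7)
  }
  const <- pip_surface(basis, c(1.5, rep(0, basis$n_p)))
  expect_equal(surface_gradient(const, random_toy_geometry()), rep(0, 15))
  # symmetric diatomic: equal and opposite forces
  d <- pip_surface(pip_basis(c(2), 1), c(0, 1))
  gd <- surface_gradient(d, c(0, 0, 0, 2, 0, 0))
  expect_equal(gd[1:3], -gd[4:6])
})

test_that("fitting recovers exactly representable surfaces", {
  set.seed(8)
  basis <- pip_basis(c(1, 2, 2), 2)
  truth <- pip_surface(basis, stats::rnorm(basis$n_p + 1, sd = 0.02))
  recs <- lapply(1:80, function(i) {
    x <- random_toy_geometry(scale = 0.4)
    list(geometry = toy_geometry(toy_high(), x),
         energy = surface_energy(truth, x), gradient = NULL, level = "gen")
  })
  fit <- pip_fit(energy_dataset(recs), basis)
  expect_lt(fit$training_rms_cm, 1e-8)
  expect_equal(fit$surface$coeffs, truth$coeffs, tolerance = 1e-8)
})

test_that("fit equals the normal-equation oracle on noisy data", {
  set.seed(9)
  basis <- pip_basis(c(1, 2, 2), 1)
  X <- lapply(1:60, function(i) random_toy_geometry(scale = 0.4))
  A <- do.call(rbind, lapply(X, function(x) {
    c(1, deltapes:::.pip_polys(basis, morse_variables(x)))
  }))
  y <- stats::rnorm(60, sd = 0.01)
  recs <- lapply(seq_along(X), function(i) {
    list(geometry = toy_geometry(toy_high(), X[[i]]), energy = y[i],
         gradient = NULL, level = "gen")
  })
  fit <- pip_fit(energy_dataset(recs), basis)
  expect_equal(fit$surface$coeffs, as.vector(normal_eq_fit(A, y)),
               tolerance = 1e-8)
})

test_that("zero-weight records do not influence the fit", {
  set.seed(10)
  basis <- pip_basis(c(1, 2, 2), 1)
  recs <- lapply(1:40, function(i) {
    x <- random_toy_geometry(scale = 0.4)
    list(geometry = toy_geometry(toy_high(), x),
         energy = stats::rnorm(1, sd = 0.01), gradient = NULL, level = "gen")
  })
  ds <- energy_dataset(recs)
  fit_all <- pip_fit(dataset_subset(ds, 1:39), basis)
  w <- c(rep(1, 39), 0)
  ds$records[[40]]$energy <- 100  # wild outlier, weight zero
  fit_w <- pip_fit(ds, basis, weights = w)
  expect_equal(fit_w$surface$coeffs, fit_all$surface$coeffs, tolerance = 1e-10)
})

test_that("gradient rows enter the fit and improve identifiability", {
  set.seed(12)
  basis <- pip_basis(c(1, 2, 2), 2)
  truth <- pip_surface(basis, stats::rnorm(basis$n_p + 1, sd = 0.02))
  recs <- lapply(1:6, function(i) {
    x <- random_toy_geometry(scale = 0.3)
    list(geometry = toy_geometry(toy_high(), x),
         energy = surface_energy(truth, x),
         gradient = surface_gradient(truth, x), level = "gen")
  })
  # 6 energies alone cannot determine 28 coefficients; 6 x (1 + 45) rows can
  expect_error(pip_fit(energy_dataset(recs), basis, use_gradients = FALSE),
               "underdetermined")
  fit <- pip_fit(energy_dataset(recs), basis, use_gradients = TRUE)
  x <- random_toy_geometry(scale = 0.3)
  expect_lt(abs(surface_energy(fit$surface, x) - surface_energy(truth, x)),
            1e-6)
})
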