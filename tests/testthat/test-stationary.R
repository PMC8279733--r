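test_that("minimum search converges on the harmonic surrogate", {
  hs <- harmonic_surface(c(700, 1200, 400), c(1836, 1836, 1836))
  m <- optimize_minimum(hs, c(0.8, -0.5, 1.2))
  expect_lt(max(abs(m$x)), 1e-6)
  expect_identical(m$order, 0L)
  # a start already at the minimum returns immediately
  m0 <- optimize_minimum(hs, c(0, 0, 0))
  expect_identical(m0$iterations, 0L)
})

test_that("double-well starts converge into their own well", {
  dw <- double_well_1d(1, 2)
  left <- optimize_minimum(dw, -0.3)
  right <- optimize_minimum(dw, 0.3)
  expect_equal(left$x, -1, tolerance = 1e-6)
  expect_equal(right$x, 1, tolerance = 1e-6)
})

test_that("saddle search finds the 1d double-well barrier top", {
  dw <- double_well_1d(1, 2)
  sp <- optimize_saddle(dw, 0.25)
  expect_equal(sp$x, 0, tolerance = 1e-8)
  expect_equal(sp$energy, 0, tolerance = 1e-12)
  expect_identical(sp$order, 1L)
  # barrier relative to the minima is the analytic b^2/(4a)
  expect_equal(sp$energy - optimize_minimum(dw, 0.5)$energy, 1, tolerance = 1e-8)
  # starting exactly at the saddle converges in place
  sp0 <- optimize_saddle(dw, 0)
  expect_identical(sp0$order, 1L)
  expect_identical(sp0$iterations, 0L)
})

test_that("toy saddle has the H equidistant from both oxygens", {
  toy <- toy_high()
  sp <- optimize_saddle(toy, toy$known$saddle + 0.01, tol = 1e-8,
                        masses = toy$masses)
  cm <- matrix(sp$x, ncol = 3, byrow = TRUE)
  r2 <- sqrt(sum((cm[1, ] - cm[2, ])^2))
  r3 <- sqrt(sum((cm[1, ] - cm[3, ])^2))
  expect_lt(abs(r2 - r3), 1e-6)
  expect_identical(sp$order, 1L)
})

test_that("harmonic analysis recovers exact quadratic frequencies", {
  hs <- harmonic_surface(c(500, 1000, 1500), c(1836, 1836, 1836))
  ha <- harmonic_analysis(hs, c(0, 0, 0), c(1836, 1836, 1836), project = FALSE)
  expect_equal(ha$frequencies, c(500, 1000, 1500), tolerance = 1e-4)
})

test_that("saddle points show exactly one imaginary frequency", {
  toy <- toy_high()
  ha <- harmonic_analysis(toy, toy$known$saddle, toy$masses)
  expect_identical(sum(ha$frequencies < 0), 1L)
  expect_identical(length(ha$frequencies), 9L)  # 3N - 6
  ham <- harmonic_analysis(toy, toy$known$minimum, toy$masses)
  expect_identical(sum(ham$frequencies < 0), 0L)
})

test_that("frequencies match an independent energy-only Hessian oracle", {
  toy <- toy_high()
  x <- toy$known$minimum
  D <- 15L
  h <- 5e-3
  H <- matrix(0, D, D)   # full second differences of the energy alone
  e0 <- surface_energy(toy, x)
  for (i in seq_len(D)) {
    for (j in i:D) {
      if (i == j) {
        xp <- x; xp[i] <- xp[i] + h
        xm <- x; xm[i] <- xm[i] - h
        H[i, i] <- (surface_energy(toy, xp) - 2 * e0 + surface_energy(toy, xm)) / h^2
      } else {
        xpp <- x; xpp[c(i, j)] <- xpp[c(i, j)] + h
        xmm <- x; xmm[c(i, j)] <- xmm[c(i, j)] - h
        xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
        xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
        H[i, j] <- H[j, i] <- (surface_energy(toy, xpp) - surface_energy(toy, xpm) -
                                 surface_energy(toy, xmp) + surface_energy(toy, xmm)) / (4 * h^2)
      }
    }
  }
  mdof <- rep(toy$masses, each = 3)
  lam <- eigen(H / outer(sqrt(mdof), sqrt(mdof)), symmetric = TRUE,
               only.values = TRUE)$values
  oracle <- sqrt(pmax(lam, 0)) * hartree_to_cm
  oracle <- sort(oracle[oracle > 5])      # drop external near-zeros
  ha <- harmonic_analysis(toy, x, toy$masses)
  got <- sort(ha$frequencies[ha$frequencies > 5])
  expect_equal(got, oracle, tolerance = 0.5 / max(oracle))
})

test_that("frequencies are invariant under rigid rotation", {
  toy <- toy_high()
  x <- toy$known$minimum
  cm <- matrix(x, ncol = 3, byrow = TRUE)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xr <- as.vector(t(cm %*% R))
  # a small step suppresses the O(h^2) anharmonic contamination that would
  # otherwise make the finite-difference Hessian frame-dependent
  ha1 <- harmonic_analysis(toy, x, toy$masses, step = 5e-4)
  ha2 <- harmonic_analysis(toy, xr, toy$masses, step = 5e-4)
  expect_lt(max(abs(ha1$frequencies - ha2$frequencies)), 0.01)
})

test_that("harmonic analysis warns away from stationary points", {
  dw <- double_well_1d(1, 2)
  expect_warning(harmonic_analysis(dw, 0.5, 1, project = FALSE),
                 "non-stationary")
})

test_that("freq_mae averages absolute differences of sorted lists", {
  expect_equal(freq_mae(c(100, 200), c(110, 190)), 10)
  expect_equal(freq_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(freq_mae(1:3, 1:4), "length mismatch")
  set.seed(15)
  a <- sort(stats::runif(12, 100, 3000))
  b <- sort(stats::runif(12, 100, 3000))
  expect_equal(freq_mae(a, b), mean(abs(a - b)))
})
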