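test_that("composition is a pointwise sum for energies and gradients", {
  low <- poly1d_surface(c(1.0))            # constant 1.0
  corr <- poly1d_surface(c(-0.25))
  comp <- compose_surfaces(low, corr)
  expect_equal(surface_energy(comp, 0.3), 0.75)
  # zero correction leaves the low level untouched
  comp0 <- compose_surfaces(double_well_1d(1, 2), poly1d_surface(0))
  set.seed(16)
  for (q in stats::runif(100, -2, 2)) {
    expect_equal(surface_energy(comp0, q), surface_energy(double_well_1d(1, 2), q))
  }
  expect_error(compose_surfaces(double_well_1d(1, 2), toy_high()), "mismatch")
  # composite gradient equals the sum of component gradients
  c2 <- compose_surfaces(double_well_1d(0.0125, 0.0165, 1836),
                         poly1d_surface(c(0, 0.001, 0.002)))
  q <- 0.4; h <- 1e-5
  gfd <- (surface_energy(c2, q + h) - surface_energy(c2, q - h)) / (2 * h)
  expect_equal(surface_gradient(c2, q), gfd, tolerance = 1e-6)
})

test_that("difference datasets re-reference both levels", {
  # one pair variable: build a low-level surface with V(ref) = 0 and
  # V(g) = 0.008
  basis <- pip_basis(c(2), 1)
  x_ref <- exp(-2 / 2); x_g <- exp(-1 / 2)
  c1 <- 0.008 / (x_g - x_ref)
  low <- pip_surface(basis, c(-c1 * x_ref, c1))
  gref <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  gg <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  high <- energy_dataset(
    list(list(geometry = gg, energy = 0.01, gradient = NULL, level = "high")),
    reference = list(geometry = gref, energy = 0))
  diff <- difference_dataset(high, low)
  expect_equal(dataset_energies(diff), 0.002, tolerance = 1e-12)
  # identical levels give an identically zero difference
  ds <- toy_datasets()
  same <- difference_dataset(ds$low, toy_pair()$low)
  expect_lt(max(abs(dataset_energies(same))), 1e-10)
  expect_error(difference_dataset(energy_dataset(high$records), low),
               "reference")
})

test_that("stride selection partitions the dataset", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  recs <- lapply(seq_len(2151), function(i) {
    list(geometry = g, energy = i * 1e-5, gradient = NULL, level = "x")
  })
  ds <- energy_dataset(recs)
  sel <- select_training(ds, 3)
  expect_identical(length(sel$train), 717L)
  expect_identical(length(sel$train) + length(sel$test), 2151L)
  # training and test are disjoint and cover the dataset
  e_all <- sort(c(dataset_energies(sel$train), dataset_energies(sel$test)))
  expect_equal(e_all, dataset_energies(ds))
  # k = 1 trains on everything
  sel1 <- select_training(ds, 1)
  expect_identical(length(sel1$train), 2151L)
  expect_identical(length(sel1$test), 0L)
  expect_error(select_training(energy_dataset(), 2), "empty")
})

test_that("energy cap and near-reference filters prune as specified", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  e_cm <- c(0, 1000, 5000, 40000, 2000, 31000, 29999, 35000, 100, 50000)
  recs <- lapply(e_cm / hartree_to_cm, function(e) {
    list(geometry = g, energy = e, gradient = NULL, level = "x")
  })
  ds <- energy_dataset(recs, reference = list(geometry = g, energy = 0))
  kept <- filter_energy_cap(ds, 30000)   # 4 of 10 exceed the cap
  expect_identical(length(kept), 6L)
  # near-reference clustering keeps structures below the RMS cutoff
  near <- toy_geometry(toy_high(), toy_high()$known$minimum)
  far <- toy_geometry(toy_high(), toy_high()$known$minimum * 1.3)
  ds2 <- energy_dataset(list(
    list(geometry = near, energy = 0, gradient = NULL, level = "x"),
    list(geometry = far, energy = 0, gradient = NULL, level = "x")),
    reference = list(geometry = near, energy = 0))
  expect_identical(length(filter_near_reference(ds2, 0.3)), 1L)
  # seeded random selection is reproducible
  expect_identical(dataset_energies(select_random(ds, 4, seed = 2)),
                   dataset_energies(select_random(ds, 4, seed = 2)))
})

test_that("database diagnostics bin energies from the dataset minimum", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  e_cm <- c(0, 100, 600, 700)
  recs <- lapply(e_cm / hartree_to_cm, function(e) {
    list(geometry = g, energy = e, gradient = NULL, level = "low")
  })
  ds <- energy_dataset(recs)
  d <- database_diagnostics(ds, ds, bin_low_cm = 500, bin_diff_cm = 500)
  expect_identical(d$hist_low$counts, c(2L, 2L))
  expect_identical(sum(d$hist_diff$counts), 4L)
  expect_identical(nrow(d$scatter), 4L)  # same geometries on both sides
  # disjoint datasets give an empty scatter without error
  g2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(3, 0, 0)))
  ds2 <- energy_dataset(list(list(geometry = g2, energy = 0, gradient = NULL,
                                  level = "diff")))
  d2 <- database_diagnostics(ds, ds2)
  expect_identical(nrow(d2$scatter), 0L)
})

test_that("difference fit recovers an exactly representable correction", {
  set.seed(17)
  pair <- toy_pair()
  basis <- pip_basis(c(1, 2, 2), 2)
  ds <- toy_datasets()
  diff <- difference_dataset(ds$high, pair$low)
  sel <- select_training(diff, 2)
  fit <- pip_fit(sel$train, basis)
  held <- vapply(sel$test$records, function(r) {
    surface_energy(fit$surface, r$geometry) - r$energy
  }, numeric(1))
  expect_lt(sqrt(mean(held^2)), 1e-6)
  # the composite reproduces high-level energies at held-out geometries
  comp <- compose_surfaces(pair$low, fit$surface)
  ref <- ds$high$reference
  for (r in sel$test$records[seq(1, length(sel$test), by = 25)]) {
    vh <- surface_energy(pair$high, r$geometry) - surface_energy(pair$high, ref$geometry)
    vc <- surface_energy(comp, r$geometry) - surface_energy(comp, ref$geometry)
    expect_equal(vc, vh, tolerance = 1e-6)
  }
  # and the composite barrier matches the analytic high-level one
  m <- optimize_minimum(comp, pair$high$known$minimum, tol = 1e-7)
  sp <- optimize_saddle(comp, pair$high$known$saddle, tol = 1e-7,
                        masses = pair$high$masses)
  expect_equal((sp$energy - m$energy) / pair$high$known$barrier, 1,
               tolerance = 0.02)
})

test_that("diagnostics report the analytic difference-energy range", {
  ds <- toy_datasets()
  pair <- toy_pair()
  diff <- difference_dataset(ds$high, pair$low)
  d <- database_diagnostics(ds$low, diff)
  ref <- ds$high$reference$geometry
  direct <- vapply(ds$high$records, function(r) {
    (surface_energy(pair$high, r$geometry) - surface_energy(pair$high, ref)) -
      (surface_energy(pair$low, r$geometry) - surface_energy(pair$low, ref))
  }, numeric(1)) * hartree_to_cm
  expect_equal(d$diff_range_cm, range(direct), tolerance = 1e-8)
})
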