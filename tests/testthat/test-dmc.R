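test_that("splitting combines repeated runs as mean difference with RSS error", {
  g <- c(26731, 26751, 26741, 26748, 26734)   # sd ~ 8.6
  e <- c(26763, 26783, 26773, 26780, 26766)
  out <- dmc_splitting(g, e)
  expect_equal(out$splitting, 32)
  expect_equal(out$uncertainty, sqrt(stats::sd(g)^2 + stats::sd(e)^2))
  # the published-style combination: means 26741/26773, sds 7 and 10
  expect_equal(sqrt(7^2 + 10^2), sqrt(149))
  expect_equal(dmc_splitting(c(1, 2, 3), c(1, 2, 3))$splitting, 0)
  expect_error(dmc_splitting(1, c(1, 2)), "at least 2")
})

test_that("identical parameters and seed give bit-identical traces", {
  hs <- harmonic_surface(0.01 * hartree_to_cm, 1)
  p <- dmc_params(300, 50, 300, dtau = 5, seed = 42)
  t1 <- dmc_ground(hs, 1, p, 0)
  t2 <- dmc_ground(hs, 1, p, 0)
  expect_identical(t1$e_r, t2$e_r)
  expect_identical(t1$positions, t2$positions)
})

test_that("a node that is never crossed reproduces the ground-state trace", {
  hs <- harmonic_surface(0.01 * hartree_to_cm, 1)
  p <- dmc_params(300, 50, 400, dtau = 5, seed = 3)
  gr <- dmc_ground(hs, 1, p, 0)
  # node far outside the sampled region, same RNG stream
  far <- dmc_node(function(X) X[, 1] + 1e6, mass = 1)
  fx <- dmc_fixed_node(hs, 1, far, p, 0, recross = FALSE)
  expect_identical(gr$e_r, fx$e_r)
})

test_that("fixed-node requires walkers strictly on one side", {
  hs <- harmonic_surface(0.01 * hartree_to_cm, 1)
  p <- dmc_params(100, 10, 50, dtau = 5, seed = 1)
  expect_error(dmc_fixed_node(hs, 1, coordinate_node(1, 1), p, 0),
               "one side")
})

test_that("walker ensemble samples the ground-state amplitude", {
  hs <- harmonic_surface(0.01 * hartree_to_cm, 1)
  tr <- dmc_ground(hs, 1, dmc_params(4000, 800, 2500, dtau = 5, seed = 21), 0)
  # unbiased DMC samples psi itself: Gaussian with variance 1/(m omega)
  expect_equal(stats::var(tr$positions[, 1]), 1 / 0.01, tolerance = 0.1)
  wh <- walker_histogram(tr, dims = 1, breaks = 40)
  expect_identical(sum(wh$counts), nrow(tr$positions))
  # symmetric double-well ground state is symmetric under q -> -q
  dw <- transfer_double_well()
  trd <- dmc_ground(dw, dw$mass, dmc_params(3000, 800, 1500, dtau = 5, seed = 22),
                    dw$known$minima[2])
  expect_lt(abs(mean(trd$positions[, 1])), 0.15)
  # all walkers at one point occupy a single bin
  wh1 <- walker_histogram(matrix(0, 50, 1), dims = 1, breaks = 10)
  expect_identical(sum(wh1$counts), 50L)
})

test_that("fixed-node energy lies above the ground state", {
  dw <- transfer_double_well()
  q0 <- dw$known$minima[2]
  p <- dmc_params(2000, 400, 2500, dtau = 5, seed = 31)
  gr <- dmc_ground(dw, dw$mass, p, q0)
  ex <- dmc_fixed_node(dw, dw$mass, coordinate_node(1, dw$mass), p, q0)
  err <- 3 * sqrt(gr$stderr^2 + ex$stderr^2)
  expect_gt(ex$energy - gr$energy, -err)
  # here the splitting is well resolved, so the ordering is strict
  expect_gt(ex$energy, gr$energy)
})

test_that("time-step bias shrinks as dtau is halved on a stiff mode", {
  hs <- harmonic_surface(0.05 * hartree_to_cm, 1)   # omega = 0.05 au
  bias <- sapply(c(10, 5, 2.5), function(dt) {
    es <- vapply(1:3, function(s) {
      dmc_ground(hs, 1, dmc_params(2000, round(2000 / dt), round(30000 / dt),
                                   dtau = dt, seed = 400 + s), 0)$energy
    }, numeric(1))
    c(mean(es) - 0.025, stats::sd(es) / sqrt(3))
  })
  expect_gt(abs(bias[1, 1]), abs(bias[1, 2]))            # dtau 10 vs 5
  expect_lt(abs(bias[1, 3]), abs(bias[1, 1]))            # dtau 2.5 vs 10
  # halving from 5 to 2.5 does not increase the bias beyond noise
  expect_lt(abs(bias[1, 3]) - abs(bias[1, 2]),
            3 * sqrt(bias[2, 2]^2 + bias[2, 3]^2))
})

test_that("population extinction raises an informative error", {
  steep <- poly1d_surface(c(0, 0, 10))    # 10 q^2: huge energies off origin
  expect_error(
    dmc_ground(steep, 1, dmc_params(5, 10, 50, dtau = 20, seed = 2), 3),
    "extinct|exploded")
})

test_that("isotope substitution shrinks the DMC splitting", {
  split_for <- function(mass_factor, seeds) {
    dw <- transfer_double_well(mass_factor)
    q0 <- dw$known$minima[2]
    g <- lapply(seeds, function(s) {
      dmc_ground(dw, dw$mass, dmc_params(1500, 400, 2000, dtau = 5, seed = s), q0)
    })
    e <- lapply(seeds, function(s) {
      dmc_fixed_node(dw, dw$mass, coordinate_node(1, dw$mass),
                     dmc_params(1500, 400, 2000, dtau = 5, seed = 50 + s), q0)
    })
    dmc_splitting(g, e)
  }
  sH <- split_for(1, 1:5)
  sD <- split_for(2, 1:5)
  # H splitting exceeds D by more than the combined uncertainties
  expect_gt(sH$splitting - sD$splitting,
            2 * sqrt((sH$uncertainty / sqrt(5))^2 + (sD$uncertainty / sqrt(5))^2))
})
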