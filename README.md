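# deltapes

Coupled-cluster-quality potential energy surfaces from cheap ones, by
additive correction — with the nuclear quantum mechanics to use them.

## Who this is for

Fitting a machine-learned potential energy surface (PES) for a molecule of
more than ~10 atoms usually means settling for MP2- or DFT-level training
data: realistic, but typically ~1 kcal/mol wrong on isomerization and
H-transfer barriers, which makes tunneling splittings badly wrong too.
`deltapes` is for people in that situation. It implements the
Δ-machine-learning construction

    V_LL→CC = V_LL + ΔV_CC−LL

where `V_LL` is the full low-level surface and `ΔV_CC−LL` is a compact
correction fitted to a few hundred high-level−low-level energy differences
spanning the same configurations. Because the correction is small and
smooth, it needs a *small* basis — which is exactly what makes it safe to
fit from little data.

The package provides, end to end:

* **PIP regression** — permutationally invariant polynomial bases in Morse
  variables `x = exp(−r/λ)` (λ = 2 bohr), enumerated by monomial-orbit
  closure under the like-atom permutation group, fitted by SVD least
  squares with optional gradient rows. A `{1,2,5,7}` designation at
  polynomial order 2 gives 85 PIPs (86 coefficients).
* **Δ-workflow** — difference datasets with explicit double re-referencing,
  stride / near-reference / energy-cap training selection, composite
  surfaces, and database diagnostics (energy histograms, difference-vs-low
  scatter).
* **Surrogates** — analytic harmonic, quartic double-well and a 5-atom
  proton-transfer toy molecule (designation `{1,2,2}`) with
  construction-time verified double wells, standing in for the
  undeposited ab initio databases so everything is testable.
* **Stationary points** — BFGS+Newton minima, eigenvector-following
  saddles, finite-difference harmonic analysis with Eckart projection, and
  the comparison metrics (all-pairs structure RMS, frequency MAE).
* **Diffusion Monte Carlo** — the simple unbiased branching algorithm for
  ZPEs, fixed-node excited states with a Gaussian-bridge recrossing
  correction, splittings with run-to-run uncertainties, walker histograms.
* **1d tunneling** — minimum-energy paths along the saddle's
  imaginary-frequency mode with frozen-coordinate masks, barrier morphing
  by uniform scaling, and sinc-DVR (Colbert–Miller) eigenvalues.

See `vignettes/delta-ml-pes.Rmd` for the methods account.

## Worked example

Fit a correction between the two levels of the built-in proton-transfer
toy, whose low-level variant underestimates the H-transfer barrier by ~35%:

```r
library(deltapes)

pip_basis(c(1, 2, 5, 7), 2)
#> <pip_basis> designation {1,2,5,7}, 15 atoms, 105 pair variables, degree <= 2: n_p = 85 orbits

pair <- proton_transfer_pair()          # "high" and "low" level toy surfaces
pair$high$known$barrier_cm              # 1901.0
pair$low$known$barrier_cm               # 1229.1

ds   <- surrogate_datasets(pair, n_low = 200, n_high = 240, del = 0.25, seed = 1)
diff <- difference_dataset(ds$high, pair$low)       # (E_high − V_LL), re-referenced
sel  <- select_training(diff, 2)                    # every 2nd point trains
fit  <- pip_fit(sel$train, pip_basis(c(1, 2, 2), 2))
fit
#> <pip_fit> 120 energy rows, 0 gradient rows; training RMS 1.093e-11 cm^-1 (rank 28)

comp <- compose_surfaces(pair$low, fit$surface)     # V_LL + ΔV
m  <- optimize_minimum(comp, pair$high$known$minimum, tol = 1e-7)
sp <- optimize_saddle(comp, pair$high$known$saddle, tol = 1e-7,
                      masses = pair$high$masses)
(sp$energy - m$energy) * hartree_to_cm
#> 1901.0      # the composite reproduces the high-level barrier
```

The training RMS is at machine precision because the toy pair's difference
potential lies exactly in the degree-2 correction span — the correction
recovers it, and the composite's saddle-minus-minimum barrier lands on the
high-level value instead of the low-level 1229 cm⁻¹.

Tunneling on the frozen reference double well (barrier 1200 cm⁻¹, proton
mass), by sinc-DVR and by DMC:

```r
dw <- transfer_double_well()
dvr_levels(path_from_surface_1d(dw, n = 301))
#> <dvr_solution> 1025 grid points; E0 = 0.0026405921, E1 = 0.0028524586 hartree; splitting 46.5 cm^-1

dmc_ground(dw, dw$mass, dmc_params(seed = 5), dw$known$minima[2])
#> <dmc_trace> ground: E = -0.0028129307 +/- 8.5e-06 hartree (-617.4 +/- 1.9 cm^-1), final N = 2008
dmc_fixed_node(dw, dw$mass, coordinate_node(1, dw$mass),
               dmc_params(seed = 6), dw$known$minima[2])
#> <dmc_trace> fixed-node: E = -0.0026072374 +/- 9.8e-06 hartree (-572.2 +/- 2.2 cm^-1), final N = 1996
```

Fixed-node minus ground gives a DMC splitting of ~45 cm⁻¹ with ~3 cm⁻¹
statistical error, consistent with the DVR value of 46.5 cm⁻¹ (energies
here are on the absolute well scale; the DVR values are referenced to the
well bottom at −0.005470 hartree).

A command-line surface over the same functions lives in
`inst/cli/deltapes.R` (`gen-surrogate`, `fit-delta`, `stationary`,
`tunnel-1d`, `dmc`).

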