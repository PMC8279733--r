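---
title: "Correcting low-level potential energy surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting low-level potential energy surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltapes)
```

# The problem

Machine-learned potential energy surfaces (PESs) for molecules beyond about
ten atoms are usually fitted to large databases of comparatively cheap
electronic energies (DFT, MP2), because coupled-cluster calculations at the
tens-of-thousands-of-points scale are prohibitive. Those cheap surfaces are
good at geometries and harmonic frequencies but systematically wrong where it
hurts most: isomerization and H-transfer barrier heights, which in turn
control tunneling splittings. `deltapes` implements the additive correction
("Δ-machine-learning") strategy for this situation:

$$ V_{\mathrm{LL}\rightarrow\mathrm{CC}} \;=\; V_{\mathrm{LL}} \;+\;
   \Delta V_{\mathrm{CC-LL}}, $$

where $V_{\mathrm{LL}}$ is the full low-level surface and
$\Delta V_{\mathrm{CC-LL}}$ is a *small, smooth* correction fitted to a modest
number of (high-level − low-level) energy differences spanning the same
configurations as the low-level database. The working assumption — and the
regime in which the approach is trustworthy — is that the difference
potential is small relative to both surfaces and varies slowly, so it can be
captured by a compact basis from hundreds rather than tens of thousands of
points. When that assumption fails, more high-level data are needed; the
database diagnostics (`database_diagnostics()`) exist precisely to inspect
the magnitude and spread of the differences before trusting a fit.

# Permutationally invariant polynomials in Morse variables

A molecular PES must be unchanged when identical nuclei are swapped. The
correction surface is therefore expanded in permutationally invariant
polynomials (PIPs): polynomials in the pairwise **Morse variables**

$$ x_{\alpha\beta} = \exp(-r_{\alpha\beta}/\lambda), $$

with $r_{\alpha\beta}$ the internuclear distance (bohr) and the range
parameter $\lambda = 2\,$bohr by default — a bounded, smoothly decaying
transform that tames the short-range wall and makes low-order polynomials
effective. One basis function is the sum of one *orbit* of monomials under
the product of symmetric groups specified by the **symmetry designation**:
the list of like-atom block sizes, e.g. `{1,2,5,7}` for a 15-atom molecule
with one unique atom and interchangeable blocks of 2, 5 and 7. The surface
is then linear in its coefficients,
$V = c_0 + \sum_i c_i\, p_i(\mathbf{x})$, and fitting is ordinary weighted
least squares.

Design choices worth stating explicitly:

* **Orbit enumeration.** Orbits are found by breadth-first closure of each
  monomial under the block *transposition generators* acting on pair
  indices. The cost is proportional to the number of monomials, not the
  group order — essential because the `{1,2,5,7}` group already has
  $2!\,5!\,7!$ = 1 209 600 elements. Full-group enumeration is retained only
  as a brute-force oracle (`pip_orbit_count_bruteforce()`) for small
  designations, and the two are cross-checked in the tests for every
  designation with up to 6 atoms at degrees 1–3.
* **Canonical representatives** are the lexicographically smallest dense
  exponent vectors in each orbit; pair variables are frozen in lexicographic
  $(\alpha<\beta)$ order, so serialized surfaces are portable.
* **Constant term.** `n_p` counts polynomial orbits only; the constant is a
  separate leading coefficient (a `{1,2,5,7}` degree-2 basis has 85 PIPs and
  86 coefficients).
* **Solver.** SVD with a relative singular-value cutoff of `1e-10`, with an
  explicit error for underdetermined systems and a warning (with the rank)
  for rank-deficient designs. The bases targeted here have at most a few
  hundred columns, so robustness is worth far more than speed.
* **Gradient rows.** When a dataset carries gradients, each of the 3N
  Cartesian components may enter as a fit row with default weight $1/3N$, so
  one geometry's gradient has total weight comparable to its energy.

# The surrogate surfaces

The real use case corrects a fitted MP2-class surface toward coupled-cluster
energies; neither database ships with this package. The `surfaces` module
therefore provides analytic stand-ins with *known* truths, and they are
first-class, tested code:

* `harmonic_surface()` — separable harmonic modes with closed-form ZPE;
  the reference for diffusion Monte Carlo correctness.
* `double_well_1d()` — the quartic $V(q) = aq^4 - bq^2$ with analytic
  barrier $b^2/4a$ and minima $\pm\sqrt{b/2a}$.
  `transfer_double_well()` freezes the package's H-transfer reference well:
  barrier 1200 cm⁻¹ and well frequency ≈1320 cm⁻¹ at proton mass, chosen to
  sit in the strong-intramolecular-H-bond regime where the H/D ground-state
  splittings (≈47 / ≈6 cm⁻¹ by sinc-DVR) are large enough to resolve with
  desk-scale DMC yet far below the well spacing.
* `proton_transfer_toy()` — a 5-atom X–O–H–O–X chain, symmetry designation
  `{1,2,2}`, built from Morse H–O bonds, harmonic O–O / O–X / 1–3
  restraints, and a coupling term $-c\,(x_{HO_2}-x_{HO_3})^2$ in Morse
  variables. Its minima, saddle and barrier are located numerically at
  construction and construction *fails* if no double well exists.
  `proton_transfer_pair()` returns a "high-level" ($c=+0.15$) and a
  "low-level" ($c=-0.15$) variant whose barriers differ by ≈35% —
  emulating the typical MP2-versus-coupled-cluster barrier mismatch. Because
  the coupling is quadratic in Morse variables with the same $\lambda$ as the
  default fit, the *difference* between the two variants lies exactly in the
  degree-2 PIP span: the Δ-fit recovery tests have a sharp, known answer.

What the surrogates deliberately do **not** emulate: electronic-structure
noise, basis-set artifacts, regions of configuration space absent from the
low-level database, and the 45-dimensional floppy-mode structure of a real
15-atom molecule. Green surrogate tests therefore certify the *machinery*
(enumeration, fitting, composition, optimization, DMC, DVR), not the
accuracy of any particular ab initio correction.

Surrogate databases are drawn by displacing every Cartesian coordinate
uniformly within ±`del` (default 0.25 bohr) around the two minima and the
saddle, under an explicit seed — the same flavor of random-grid sampling
used to densify real training databases near stationary points.

# Training-set selection

`select_training()` implements stride selection: 0-based indices
$0, k, 2k, \dots$ train and the rest test, so 2151 records at $k=3$ give
717 training points; the subsets are disjoint and exhaustive by
construction. `filter_near_reference()` keeps structures whose RMS
difference over all $\binom{n}{2}$ internuclear distances (the same metric
as `structure_rms()`, reported in Å) is below a cutoff — "bond lengths"
here always means *all pairs*, 105 of them for 15 atoms.
`filter_energy_cap()` drops records above an energy cap (cm⁻¹ relative to
the dataset reference), and `select_random()` is the seeded random picker.
Energy referencing is explicit everywhere: difference datasets re-reference
*both* levels at the same reference geometry before subtracting, so the
correction is zero there by construction.

# Stationary points and harmonic analysis

Minima: BFGS followed by Newton polishing with eigenvalue clamping, to a
gradient max-norm of $10^{-6}$ hartree/bohr. Saddles: eigenvector-following
Newton steps — the lowest non-zero Hessian mode is walked uphill, all others
downhill — optionally in mass-weighted coordinates; convergence to anything
other than exactly one negative eigenvalue is an error that reports the
signature. Hessians are central finite differences of the analytic gradient
with step $5\times10^{-3}$ bohr; translational/rotational modes are removed
with the standard Eckart-frame projector (6 modes, or 5 for linear
arrangements, detected by QR rank). Imaginary frequencies are stored as
negative numbers and printed with an "i" suffix. The finite-difference step
trades anharmonic contamination ($O(h^2)$) against round-off; at the default
step, frequencies are frame-dependent at the few-tenths-of-cm⁻¹ level, which
is why the rotational-invariance test uses a smaller step ($5\times10^{-4}$
bohr) where that contamination is below 0.01 cm⁻¹.

# Diffusion Monte Carlo

`dmc_ground()` implements the simple unbiased branching algorithm: walkers
diffuse with per-coordinate Gaussian steps of variance $\Delta\tau/m$; a
walker with potential $E_i$ below the reference energy $E_r$ births with
probability $e^{-(E_i-E_r)\Delta\tau} - 1$ (integer part forced, fraction
sampled, at most `max_birth = 3` extra copies), one above $E_r$ dies with
probability $1 - e^{-(E_i-E_r)\Delta\tau}$; then
$E_r \leftarrow \langle V\rangle - \alpha\,(N(\tau)-N(0))/N(0)$ with
$\alpha = 1/\Delta\tau$ by default. The production-time average of $E_r$
estimates the ZPE. Defaults (2000 walkers, 500 equilibration and 5000
production steps, $\Delta\tau = 5$ au) are scaled-down versions of
production-style runs (30 000 walkers, 50 000 steps) that keep every suite
affordable on one CPU; statistical errors come from 50-block standard
errors within a run, and run-to-run standard deviations across seeds for
splittings.

`dmc_fixed_node()` adds the fixed-node excited state: walkers whose node
function changes sign are removed, and with `recross = TRUE` a surviving
walker is additionally killed with the Gaussian-bridge probability
$\exp(-2\,d\,d'\,\bar m/\Delta\tau)$, where $d, d'$ are node distances
before and after the move. For the H-transfer node
$r_{HO_a} = r_{HO_b}$ (`distance_difference_node()`), the node-direction
effective mass $\bar m$ is taken as the H–O reduced mass — the node normal
is not uniquely defined in Cartesian coordinates, and this choice is the
simplest mass consistent with the distance-difference coordinate; the
correction is toggleable precisely so its influence can be measured. On the
reference double well the recrossing correction moves the excited estimate
by several cm⁻¹, onto the sinc-DVR value.

Two empirical notes, both verified in the tests: (i) the walker ensemble
samples the wave function $\psi$ itself, not $|\psi|^2$ — for a harmonic
mode the walker-position variance is $\hbar/(m\omega)$, and the histogram
test asserts exactly that; (ii) the time-step bias of this branching scheme
is remarkably small at the default $\Delta\tau$ — on the soft surrogate
wells it is below ≈1 cm⁻¹, *smaller than affordable statistical resolution*,
so the bias-shrinks-with-$\Delta\tau$ property is asserted on a stiff
$\omega = 0.05$ au mode where the first-order bias is unambiguous.

Splittings combine repeated independent runs per state:
mean(excited) − mean(ground), with the root-sum-square of the two
run-to-run standard deviations as the quoted uncertainty — deliberately the
simple estimator matching how repeated DMC runs are usually reported,
rather than a blocked autocorrelation analysis.

# 1d tunneling: Q_im paths, morphing, sinc-DVR

`qim_path()` builds the 1d minimum-energy cut along the saddle's
imaginary-frequency normal mode: displace by $q$ (mass-scaled,
bohr·$\sqrt{m_e}$) along the mode, hold any masked coordinates at their
saddle values (the treatment for internal-rotor coordinates that
rectilinear normal modes cannot follow), and relax the remaining degrees of
freedom in the subspace orthogonal to the displacement direction. Paths are
stored mass-scaled with effective mass 1, so isotope substitution is a
$\sqrt{m_{\mathrm{new}}/m_{\mathrm{old}}}$ stretch of the abscissa
(`path_rescale_mass()`).

A constrained 1d cut generally misses the true barrier (frozen coordinates
and fitting error both contribute), so `morph_path()` rescales the path
energies uniformly to an externally known barrier height. Uniform scaling is
the simplest morph that fixes the barrier while preserving the well
geometry; coordinate-dependent morphs are out of scope, and the applied
factor is recorded in the object.

`dvr_levels()` solves the 1d Schrödinger equation with the sinc-DVR
(uniform-grid Colbert–Miller kinetic matrix) on a natural-cubic-spline
interpolant of the path, doubling the grid until $E_0$ and $E_1$ move by
less than 0.01 cm⁻¹ (default start 513 points, at most 4 doublings, error
with the last change otherwise). The independent cross-check in the tests
is a dense central-difference Hamiltonian with Richardson extrapolation —
a different discretization family, agreeing to well under 0.01 cm⁻¹ on the
reference well.

# Problem sizes

The suites run at deliberately modest sizes, chosen once: surrogate
databases of 200–300 geometries (the correction basis has 27 terms at
`{1,2,2}` degree 2, so hundreds of points already overdetermine it by an
order of magnitude); DMC at 1500–4000 walkers and a few thousand steps;
DVR grids of 301–1025 points; the held-out-RMS trend uses an 800-point
master grid with stride-selected training sets of 50–400 and 10 averaged
noise replicates. These sizes keep each statistical assertion at the
3-standard-error level it is tested at.

# Known limitations

* The correction basis must share the atom ordering of its symmetry
  designation; `atom_order` mapping is the caller's responsibility when
  datasets are numbered differently.
* Degree ≥ 4 bases at 15 atoms are outside the intended range (orbit
  enumeration over all monomials becomes the bottleneck); fragmented-basis
  techniques for larger molecules are not implemented.
* The DMC driver evaluates analytic surrogates in vectorized batches, but
  falls back to row-wise evaluation for PIP surfaces — production-scale DMC
  on a fitted 15-atom surface would want a compiled evaluation path.
* Fixed-node energies are upper bounds only as good as the node; the
  distance-difference node is exact only when the true nodal surface
  coincides with $r_{HO_a} = r_{HO_b}$.
* Uniform-scaling morphs preserve well positions but not curvatures at
  fixed barrier; splittings inherit that approximation.
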