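Package: deltapes
Title: Delta-Machine-Learning Potential Energy Surfaces with PIP Regression,
    Diffusion Monte Carlo and 1d Tunneling Splittings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building coupled-cluster-quality potential energy
    surfaces by additive delta-machine-learning correction of a lower-level
    surface. Provides permutationally invariant polynomial (PIP) bases in
    Morse variables with orbit enumeration, linear least-squares fitting with
    optional gradient data, composite (low-level plus correction) surfaces
    with training-set selection rules and database diagnostics, analytic
    surrogate surfaces with known barriers and spectra, minimum and
    saddle-point optimization with harmonic normal-mode analysis, unbiased
    and fixed-node diffusion Monte Carlo for zero-point energies and
    hydrogen-transfer tunneling splittings, and one-dimensional sinc-DVR
    eigenvalues on morphed minimum-energy paths.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
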