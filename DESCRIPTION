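Package: neurofield
Title: Two-Layer Neural Field Modeling of Voltage-Sensitive Dye Imaging Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and identification of a two-layer (excitatory/inhibitory)
    Wilson-Cowan/Amari neural field model of mesoscopic visual-cortex dynamics as
    captured by voltage-sensitive dye (VSD) imaging. Provides cortical-coordinate
    stimulus construction for flashed, line-motion and moving stimuli; an
    explicit-Euler field integrator with Gaussian lateral coupling; an affine
    excitation/inhibition observation model fitted by constrained least squares;
    grid-search plus CMA-ES parameter identification; single-layer Amari and
    feed-forward control models with AIC comparison; linear stability analysis of
    the homogeneous state in Fourier space; response analyses (superposition
    nonlinearity, layer correlations, wavefront propagation speed); and a
    synthetic VSD recording generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
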