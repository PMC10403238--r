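Package: sptddm
Title: Particle Transport Analysis by Single-Particle Tracking and
    Differential Dynamic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes anomalous particle transport in crowded and
    active soft matter from two complementary observables: real-space
    single-particle tracking (ensemble time-averaged mean-squared
    displacements with multi-phasic regime detection, and van Hove
    displacement distributions with Gaussian-plus-exponential mixture
    fits, width and asymmetry statistics) and reciprocal-space
    differential dynamic microscopy (radially averaged image structure
    functions, stretched-exponential decay fits, and tau(q) power-law
    scaling). Includes a synthetic-data module that generates
    trajectories with exact fractional Brownian motion statistics,
    ballistic and caged-hopping motion, and renders them into
    microscopy-like image stacks, so every analysis stage can be
    validated against known transport parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
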