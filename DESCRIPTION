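Package: mptrheo
Title: Multiple-Particle-Tracking Microrheology and Quantitative Cell
    Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for live-cell mechanics analysis by multiple-particle
    tracking microrheology: simulation of probe-particle trajectories in
    viscous, power-law viscoelastic (fractional Brownian), and
    harmonically trapped media with exact covariance; rendering of
    synthetic fluorescence movies and stained-cell images; sub-pixel
    intensity-weighted centroid particle localization and
    nearest-neighbour trajectory linking; mean-squared-displacement
    estimation and conversion to frequency-dependent viscoelastic moduli
    through the generalized Stokes-Einstein relation with the local
    power-law (Mason) estimator; cell, nuclear and stress-fiber
    morphometry from fluorescence images; and plate-assay statistics
    (centrifugal adhesion fractions, delta-delta-Ct fold changes, group
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
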