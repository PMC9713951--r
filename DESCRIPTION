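Package: lambpress
Title: Internal Pressure Estimation from Acoustoelastic Lamb-Wave Dispersion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the internal pressure of a fluid-filled, thin-walled
    spherical biological compartment (such as the bladder) from
    frequency-resolved Lamb-wave phase velocities. Couples finite-deformation
    pressure-vessel mechanics under a Demiray-Fung constitutive model with a
    pre-stressed, fluid-loaded (leaky) Lamb-wave dispersion relation, and
    inverts the relation by simplex curve fitting. Includes the
    wavefield-to-dispersion processing chain (autocorrelation particle
    velocity, median filtering, wall-profile extraction, 2D-FFT k-space phase
    velocity), seeded synthetic-data generators for every input, and
    evaluation statistics (RMSD, mean error, relative mean error, mean
    phase-velocity variance, and Lin's concordance correlation coefficient
    for repeated measures from variance components).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
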