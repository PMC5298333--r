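Package: mesospectra
Title: Plankton Particle Size Spectra from Mesocosm CO2 Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build normalized particle size spectra (PSS) and
    weighted biomass spectra (WBS) of plankton communities spanning
    picophytoplankton to mesozooplankton (~0.5 um to >1 mm equivalent
    spherical diameter), as measured in CO2-perturbation mesocosm
    experiments. Converts flow-cytometry forward scatter to cell size via a
    power-law calibration fitted from size-fractionation data, segments and
    measures greyscale zooplankton scan plates, scales counts to in-situ
    concentrations through the net-tow sampling geometry, bins particles
    into logarithmically spaced size classes, fits log-log spectrum slopes,
    and compares treatments per size class with two-sample t-tests guarded
    by variance-homogeneity and normality checks. A seeded synthetic
    community simulator reproduces the temporal structure of a
    winter-to-summer plankton succession (bloom waves, copepod cohort
    shifts, treatment effect multipliers) so that every pipeline stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
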