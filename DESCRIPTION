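Package: gridheat
Title: Heat Transport Modelling and Support-Grid Selection for Cryogenic
    Fluorescence Microscopy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state and transient heat-transport modelling of
    laser-illuminated cryo-TEM support grids. Predicts sample temperature
    profiles across grid squares, devitrification thresholds and damage
    extents for arbitrary grid and holey-film designs; calibrates effective
    film absorption parameters from (possibly censored) maximum-illumination
    power-density measurements; checks the carbon-fraction scaling law;
    compares mesh, bar-metal and film-material choices; and ranks candidate
    grids for correlated cryogenic light and electron microscopy. Includes a
    synthetic-data generator for threshold-measurement studies and power-ramp
    experiments so the full calibration pipeline can be validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
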