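Package: planktonshift
Title: Plankton Range Shifts Versus the Velocity of Climate Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for testing thermal niche plasticity versus
    conservatism in marine plankton from ship-of-opportunity survey data.
    Tow samples are binned into 5-year by monthly sets, log-transformed and
    interpolated to a regular 0.5 degree grid by ordinary kriging with
    automatic variogram model selection; sea surface temperature is kriged
    to the same grid and the latitudes of reference isotherms (11, 12 and
    13 degrees C by default) are tracked through time by per-longitude
    polynomial regression.  For each taxon the package derives the
    percentage of the population north of each isotherm, the median range
    latitude, a population index, displacement and per-decade velocity
    statistics, and tests the percent-north series against isotherm
    latitude using Pearson correlations with effective degrees of freedom
    adjusted for serial autocorrelation.  Seasonal peak timing and
    phenological shifts are computed from monthly abundance profiles.  A
    synthetic-data module generates sea surface temperature fields and
    Continuous Plankton Recorder style tow samples with known niche
    behaviour so the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
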