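Package: cropnsim
Title: Daily Crop Production and Nitrate Leaching Simulation for
    Maize-Wheat Double Cropping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A one-dimensional daily soil-vegetation-atmosphere simulator
    for crop production and nitrate leaching in intensive maize - winter
    wheat double crop rotations on deep silty loam soils, parameterised
    for the North China Plain.  Couples Richards-equation soil water flow
    with van Genuchten-Mualem hydraulics, FAO-56 reference
    evapotranspiration, crop phenology, canopy photosynthesis and
    nitrogen uptake, a multi-pool soil organic matter turnover network
    (mineralisation, immobilisation, nitrification, denitrification,
    ammonia volatilisation), and convection-dispersion solute transport.
    Also provides the classical field estimators (water-balance drainage
    and concentration-weighted nitrate leaching), goodness-of-fit
    statistics (RMSR, mean deviation, Nash-Sutcliffe efficiency, R2),
    one-at-a-time sensitivity analysis, fertiliser-ladder scenario
    analysis, and a seeded synthetic weather generator for the
    semi-arid monsoonal climate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
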