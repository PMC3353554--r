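Package: phenokrige
Title: Geostatistical Analysis of Flowering Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the geostatistical analysis of plant flowering
    phenology from sparse monitoring networks: phenophase scoring on the
    0-4 flowering scale, descriptive screening with m +/- 3s outlier
    thresholds, empirical semivariogram estimation, Gaussian isotropic
    variogram model fitting (r2, RSS), simple kriging point and grid
    interpolation, leave-one-out cross-validation with estimated-versus-
    actual regression, phenological raster maps with full-flowering band
    classification, and weekly airborne pollen index aggregation.  A
    synthetic-data generator emulates spatially autocorrelated phenophase
    fields with an altitude-driven delay so the whole pipeline is testable
    without field data.  Rasters are exchanged as ESRI ASCII grids and all
    tables as delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
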