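Package: soilspatial
Title: Geostatistics of Soil CO2 Emission and Soil Attributes on Regular Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geostatistical analysis of soil CO2 efflux (FCO2) and soil
    physical, chemical and microbiological attributes surveyed on regular
    point grids, as practised in sugarcane field-reform studies. Provides
    empirical semivariogram estimation (Matheron estimator), weighted
    least-squares fitting of spherical, exponential and gaussian models,
    spatial-dependence-index classification, ordinary kriging with
    leave-one-out cross-validation, derived soil-carbon quantities (total
    organic carbon, carbon stock, daily C-CO2 emission, decay constant),
    delineation of contrasting-emission regions from kriged maps, and a
    two-group statistical battery (pooled t tests, Hotelling's T2, Ward
    clustering, correlation-matrix PCA). A synthetic-data module simulates
    Gaussian random fields with the configured variogram structure and
    two-region microbiological tables, so the whole pipeline is testable
    without field data.
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
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
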