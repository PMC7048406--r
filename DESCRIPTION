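Package: grassinvert
Title: Grassland Aboveground Biomass Estimation from Ground and Satellite NDVI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage empirical inversion of satellite NDVI to grassland
    aboveground biomass (AGB). Converts ground hyperspectral reflectance to
    broadband NDVI, fits and compares four regression families (linear,
    logarithmic, power, exponential) of AGB against ground NDVI, calibrates
    satellite NDVI against plot-mean ground NDVI by plot-level linear
    regression, composes both fits into a single exponential inversion model,
    applies it to NDVI rasters with nodata propagation and saturation
    flagging, and validates predictions at held-out locations with
    root-mean-square (SE) and mean relative (MEC) error statistics. Includes
    a seeded synthetic field-campaign generator (linear spectral mixing of
    vegetation and soil endmembers) so the full pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
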