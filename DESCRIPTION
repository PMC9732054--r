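Package: lulcst
Title: Land-Use/Land-Cover Change and Land Surface Temperature Analysis from
    Landsat-Style Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for two-date land-use/land-cover (LULC) change
    analysis from Landsat-style multispectral scenes: radiometric conversion of
    thermal digital numbers to top-of-atmosphere radiance and brightness
    temperature, NDVI, proportion of vegetation, NDVI-based emissivity, and
    single-channel land surface temperature (LST) retrieval; Gaussian maximum
    likelihood classification of band composites from labeled training points;
    error-matrix accuracy assessment (producer's/user's/overall accuracy,
    Cohen's Kappa); per-class area tabulation with two-date change statistics
    and annual rates; and per-class LST-NDVI bivariate regression. Includes a
    synthetic-scene generator with known class truth so the full chain is
    testable without satellite data, and plain-text (ESRI ASCII Grid) raster
    input/output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
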