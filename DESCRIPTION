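Package: soc3d
Title: Three-Dimensional Soil Organic Carbon Stock Mapping for Alpine Grasslands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating three-dimensional soil organic carbon (SOC)
    stocks in alpine grassland soils where a mat-like organic surface horizon
    (the mattic epipedon) concentrates carbon near the surface. Provides a
    step-wise exponential depth function with a surface plateau, per-profile
    nonlinear fitting, pedo-transfer estimation of bulk density, random-forest
    prediction of the depth-function parameters from environmental covariate
    rasters, closed-form depth integration into SOC stock maps for arbitrary
    depth layers, validation indices (mean error, RMSE, Lin's concordance
    correlation coefficient) with repeated-run summaries, a residual
    semivariogram check, and a seeded synthetic-data generator so the whole
    pipeline can be exercised and benchmarked without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
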