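Package: nppimpact
Title: Decomposing Urbanization Impacts on Vegetation Productivity with
    Spatial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates the impact of urban expansion on vegetation net
    primary productivity (NPP) into a direct component (replacement of
    vegetated surface by impervious surface) and an indirect component
    (altered growth conditions, e.g. urban-heat-island warming) on a
    regular fishnet grid. Provides global and local Moran's I with
    permutation inference and LISA cluster classification, an ordinary
    least squares baseline, and geographically weighted regression with a
    bi-square kernel and adaptive bandwidth selected by AIC, so that the
    spatially varying effect of land surface temperature on the indirect
    NPP component can be mapped. Includes a synthetic-city raster
    generator with known ground truth for end-to-end validation, a
    plain-text raster reader/writer, fishnet aggregation, and a
    single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
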