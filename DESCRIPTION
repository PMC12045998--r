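Package: aprmap
Title: High-Resolution Pesticide Application-Rate Mapping for the EU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs 250 m pesticide application-rate maps for the
    European Union from coarse first-guess application-rate grids, a
    high-resolution crop map and country-level applied-mass statistics.
    Implements categorical crop-raster fusion and modal upscaling,
    nearest-neighbour projection of coarse rate grids, maximum-likelihood
    calibration of a crop-by-region scaling model with Gauss-Newton
    posterior uncertainty, Monte-Carlo propagation into Low/Median/High
    scenario rasters, and per-pixel data-quality indexing. A synthetic-data
    module generates all pipeline inputs with known ground truth so every
    stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
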