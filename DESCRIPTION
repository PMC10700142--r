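Package: forestpotential
Title: Bottom-Up Assessment of Current and Potential Forest Carbon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for estimating current and potential forest
    carbon stocks and the deficit between them, from tree-level allometry
    through plot- and pixel-level carbon densities to counterfactual
    potential-carbon models that statistically remove the human footprint.
    Includes ensemble random-forest modelling with spatial bootstrap
    subsampling, the accompanying diagnostics (Moran's I residual
    autocorrelation, spatially buffered leave-one-out cross-validation,
    PCA convex-hull extrapolation mapping, partial regression along the
    human-disturbance gradient), scaling of living tree carbon to full
    ecosystem pools (roots, dead wood and litter, soil), partitioning of
    the carbon deficit into conservation and restoration components across
    land-cover classes, a six-source uncertainty budget, and a synthetic
    world generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ranger,
    geosphere,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
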