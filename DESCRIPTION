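Package: shearcolony
Title: Single-Cell Analysis of Bacterial Growth and Adhesion Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell analysis of bacterial surface colonization
    under fluid flow: an agent-based simulator of rod-shaped cell monolayers
    with dividing, lagged-dividing and non-dividing phenotypes, a synthetic
    phase-contrast frame renderer, image segmentation (background model,
    difference-of-Gaussians bandpass, thresholding, ellipse and pole
    extraction), trajectory linking with gap closing, division and
    detachment/attachment event detection, mean-square-displacement
    phenotype classification, population growth-rate decomposition into
    division, detachment and reattachment contributions, the bistable
    divider-fraction growth model, and laminar duct-flow shear and
    nutrient-transport calculations for rectangular microchannels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
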