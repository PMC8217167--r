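Package: canopyN
Title: Histogram-Based Nitrogen Diagnosis from Crop Canopy RGB Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nitrogen-status diagnosis for cereal canopies from nadir RGB
    photographs. Computes six per-pixel color indices (G/R, G/B, normalized
    R/G/B intensities and the normalized green-minus-red index), extracts
    either index-image mean values (IIMV) over the vegetation component or
    index-image histogram (IIH) features with soil/vegetation peak detection
    and correlation-based bin selection, and trains a small multilayer
    perceptron by Levenberg-Marquardt least squares to predict leaf nitrogen
    content and grain yield. Includes a synthetic canopy-image generator that
    emulates soil/vegetation pixel mixtures with nitrogen-dependent greenness
    and fractional coverage, camera color transforms, and an evaluation
    harness comparing the two feature families on train/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ImageProcessing, Regression, Agriculture
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'canopyN-package.R'
    'color-index.R'
    'image-io.R'
    'synthetic-canopy.R'
    'nn-model.R'
    'features.R'
    'evaluation.R'
    'cli.R'
    'utils.R'
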