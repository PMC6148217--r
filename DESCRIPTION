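Package: pluckseg
Title: Multi-Part Segmentation of Offal Images with Auto-Context and
    Adaptive Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Iterative multi-class segmentation of vertically hung organ
    groups ("plucks") in colour images, built around the auto-context
    algorithm. Each iteration trains a multi-layer perceptron on local
    Haar-wavelet appearance features concatenated with class-probability
    context sampled on a sparse star stencil. Two extensions are provided:
    integral context features (row-wise and image-wise average class
    probabilities) and a weighted atlas that is re-estimated per image at
    every iteration as a similarity-weighted combination of training
    annotations. Includes organ-level (Dice) and pixel-level (confusion
    matrix, quadratic score) evaluation, a cross-validation harness, and a
    synthetic pluck-image generator so the whole pipeline is testable
    without proprietary abattoir data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
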