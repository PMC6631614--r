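Package: cocoonsort
Title: Gender Classification of Silkworm Cocoons from Backlit Silhouettes and Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-processing and machine-learning pipeline for sorting
    silkworm (Bombyx mori) cocoons by gender, as performed at sericulture
    grainage centers. Provides a synthetic generator of backlit cocoon
    silhouette images with breed- and gender-conditional weights, Otsu
    binarization with a single-cocoon area gate, the nine-component
    weight-plus-shape integrated feature vector (area, perimeter, moment
    ellipse axes, eccentricity, circularity, rectangularity, solidity,
    convexity), z-score normalization fitted on training data, a linear
    soft-margin support vector machine classifier, and a full evaluation
    protocol (stratified hold-out split, confusion-matrix metric suite,
    repeated-trial repeatability statistic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
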