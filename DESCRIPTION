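Package: texhawk
Title: Hybrid Texture and Deep Feature Classification with Harris Hawks
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of grayscale medical images (e.g. brain MRI
    slices in Alzheimer's disease studies) through a hybrid pipeline: gray-level
    co-occurrence matrix (GLCM) texture statistics fused with features from a
    pluggable deep convolutional backend, wrapper feature selection driven by
    Harris Hawks Optimization (HHO) with an error-plus-sparsity cost evaluated
    by a small perceptron, and a long short-term memory (LSTM) classifier
    trained by gradient descent. Includes synthetic fixture generators for
    two-class textured images and planted-signal feature tables, FWHM-based
    Gaussian preprocessing, stratified splitting, and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    tools,
    utils
Suggests:
    optparse,
    png,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
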