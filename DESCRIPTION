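Package: spikecount
Title: Local Count Regression Networks for Counting Plants in Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting dense, non-rigid objects (wheat spikes, maize tassels)
    in field images by context-augmented local count regression. Converts dot
    annotations into Gaussian density maps and window-integrated local-count
    targets, builds and trains small AlexNet-like convolutional regressors in
    both patch-based and fully convolutional forms, merges overlapping window
    predictions into a normalized count map whose integral is the image count,
    and provides analytic receptive-field, FLOPs and parameter accounting for
    sequential convolutional architectures. Includes a seeded synthetic
    field-scene generator so the full pipeline runs end-to-end without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
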