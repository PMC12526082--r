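Package: spikedet
Title: Lightweight Wheat-Spike Detection: Architecture, Data Pipeline and
    Counting Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for building and auditing a lightweight single-stage
    wheat-spike detector and its data pipeline. Implements the bespoke network
    blocks (mixed-aggregation feature enhancement with spatial attention, a
    bidirectional asymmetric feature pyramid, adaptive downsampling, and a
    group-normalized shared detection head) on a small reverse-mode tensor
    layer, assembles the module-ablation ladder and reproduces its parameter
    and FLOP figures, tiles and splits field imagery with overlap and white
    padding, generates synthetic wheat-field scenes with a controllable object
    scale mixture, and evaluates detections with COCO-style average precision
    and spike-counting error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
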