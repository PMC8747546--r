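Package: ecgad
Title: Anomaly Detection in Fixed-Length ECG Heartbeats with Attention
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects anomalous heartbeats in fixed-length (140-sample)
    single-lead ECG records of the ECG5000 kind. Implements three detectors:
    a dense autoencoder with a sigmoid-gated concatenation-attention
    bottleneck, a variational autoencoder with a two-dimensional Gaussian
    latent space, and a two-layer LSTM binary classifier, all trained with
    hand-derived backpropagation and the Adam optimizer. Reconstruction
    models are converted into binary detectors by training on normal beats
    only and thresholding the per-record reconstruction error at one
    standard deviation above its training mean. Includes a UCR-archive-style
    reader/writer, min-max normalization fitted on the training split,
    deterministic dataset splitting, a synthetic ECG-beat generator for
    self-contained experiments, confusion-matrix metrics, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
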