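Package: breathpd
Title: Parkinson's Disease Detection and Severity Tracking from Nocturnal Breathing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects Parkinson's disease and estimates MDS-UPDRS severity from
    one-dimensional nocturnal breathing signals (respiratory-effort belts or
    contactless acquisition). Implements a multitask neural network -- a 1D
    bottleneck-residual convolutional encoder with simple recurrent units,
    self-attention temporal pooling, classification and severity heads, a
    UNet-style quantitative-EEG decoder used as auxiliary supervision,
    domain-adversarial discriminators for belt/wireless transfer and a
    transductive consistency regularizer -- together with Platt-scaled
    four-fold ensemble calibration, the multi-night evaluation methodology
    (median aggregation, Guttman-style intraclass correlation test-retest
    reliability, exact rank tests, progression statistics), attention-based
    interpretation by sleep stage and EEG band, and a synthetic
    polysomnography simulator so the full pipeline runs end to end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
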