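Package: phecare
Title: Privacy-Preserving Disease Detection with Homomorphic Storage and a
    Whale-Optimised Centered Convolutional RBM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for privacy-preserving classification of tabular
    patient records. Feature vectors are stored under partially homomorphic
    encryption (an additive Paillier scheme and a multiplicative textbook
    RSA scheme, with fixed-point encoding of real features), and disease
    labels are predicted by a centered convolutional restricted Boltzmann
    machine with probabilistic max-pooling, trained by centered contrastive
    divergence. Initial model parameters are selected by the whale
    optimization algorithm. Includes a seeded synthetic cohort generator,
    confusion-matrix and timing metrics, a dictionary-attack security
    analysis, and an end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
SystemRequirements: OpenSSL (libcrypto)
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
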