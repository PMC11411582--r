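Package: eventseg
Title: Event Segmentation Analyses for Temporal Community Structure EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing, simulating, and analysing EEG experiments on
    event segmentation under temporal community structure. Builds the 15-node
    three-community graph and its exposure/parsing stimulus sequences (random
    walks, forced-exit pseudorandom walks, Hamiltonian paths, boundary-swap
    manipulations, posttest), simulates multi-channel scalp EEG and behaviour
    with planted condition effects as recoverable ground truth, and implements
    the analysis chain: filtering, ICA-based ocular artifact removal, epoching,
    peak-to-peak artifact rejection, Morlet wavelet spectral features, P300
    window statistics with permutation contrasts, PCA feature selection with
    Kaiser retention, L2-penalised logistic decoding with covariance-based
    feature importance, cross-community predictive classification, and
    lag-matched representational pattern similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
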