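Package: kfcs
Title: Brain-Network Features for Emergency-Braking Intention Detection from EEG
Version: 0.1.0
Authors@R: person("KFCS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Detects emergency-braking versus normal-driving brain states from
    multichannel EEG epochs. Builds functional connectivity networks with
    cross-sample entropy (CsEn), binarizes them at a swept threshold, ranks
    channels with the K-order propagation number node-importance algorithm,
    and classifies epochs with an RBF-kernel support vector machine under
    stratified cross-validation. Includes threshold selection via the general
    optimal threshold value (GOTV), k-nearest-neighbour channel grouping with
    leave-one-out core-node selection, and a synthetic multichannel generator
    with class-dependent hub coupling so the full pipeline is testable without
    real recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
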