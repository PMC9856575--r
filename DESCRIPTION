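Package: coiwave
Title: Cone-of-Influence-Aware Wavelet Scalogram Classification of ERP/EEG Signals
Version: 0.1.0
Authors@R: person("The coiwave developers", role = c("aut", "cre"),
    email = "coiwave@example.org")
Description: Tools for building event-related potential (ERP) and EEG
    classifiers from continuous wavelet transform (CWT) scalograms while
    accounting for the cone of influence (COI), the boundary separating
    accurately computed wavelet coefficients from edge-effect artifacts.
    Provides an analytic Morlet CWT with explicit full/same/valid
    convolution-mode semantics, COI delineation and scalogram quality
    ratios, extraction of whole (S), zeroed (Z), cropped (V) and
    complement (V-bar) scalogram feature vectors, m-subsample-averaged
    ERP ensemble generation for single-subject classifier design with
    leakage-free cross-validation, rank-of-rank-sum channel selection,
    a uniform interface over six classifier families (RBF support vector
    machine, random forest, k-nearest neighbour, multilayer perceptron
    and two convolutional network variants), an experiment harness for
    multi-run cross-validated comparisons, and a synthetic two-class
    oscillatory trial generator so every stage is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
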