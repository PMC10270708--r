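Package: stfc
Title: Spatiotemporal Transformers for Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns contextual representations of multivariate BOLD-like time
    series together with their sliding-window dynamic functional connectivity
    (dFC) networks. Implements a spatiotemporal transformer: sinusoidal and
    connectomic positional embedding, multi-head dot-product graph attention,
    Chebyshev graph convolution on per-window Pearson networks, sigmoid-gated
    fusion of the two branches, stacked spatial/temporal blocks with residual
    chaining, and a convolutional prediction head trained by backpropagation
    through a built-in reverse-mode differentiation tape. Includes a synthetic
    two-class resting-state cohort generator with planted subnetwork coupling,
    subject-level stratified splitting, segment batching, ensemble majority
    voting, and evaluation tools (ROC AUC, confusion matrices, fast DeLong
    paired AUC test, attention-map extraction and averaging, mean-percentage-
    error map similarity, and window/overlap sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
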