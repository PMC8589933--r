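Package: catrace
Title: Functional Fingerprinting of Calcium-Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of cell-by-frame calcium fluorescence
    traces: min-max normalization, packed real-DFT log-magnitude spectral
    features with a sum-of-squared-differences frequency-cutoff criterion,
    exact one-dimensional Earth Mover's Distance (with partial matching)
    between spectra, complete-linkage hierarchical clustering with the
    agglomerative coefficient, silhouette and an EMD-adapted Davies-Bouldin
    index, k-Shape motif extraction from detected calcium peaks with
    Markov-chain modelling of motif sequences, stimulus tuning curves and
    linear-discriminant state projections, and seeded synthetic generators
    of calcium traces, stimulus sessions and peak libraries with known
    ground truth. Includes UUID-tagged provenance logging for analysis
    lineage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
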