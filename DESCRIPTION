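Package: cicada
Title: Consensus Independent Component Analysis for Bulk Omics Deconvolution
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolution of bulk transcriptome and miRNome expression
    matrices into statistically independent components by consensus FastICA
    with leave-one-sample-out resampling and per-component stability
    estimation. Downstream machinery covers significance calling of
    top-contributing features from median/MAD z-scores, component
    orientation, a survival-weighted risk score built from per-component
    Cox screens, quantile ranking-score projection of new samples onto a
    discovery cohort, and correlation-based linking of components across
    omics layers. Includes a synthetic-data generator with known ground
    truth (non-Gaussian sources, batch offsets, survival and class-label
    drivers) so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
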