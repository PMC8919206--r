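Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for RT-qPCR
    normalization. Implements the four classical expression-stability
    algorithms from their mathematical definitions -- geNorm (M-value,
    iterative exclusion, normalization factors and pairwise variation V),
    a model-based NormFinder-style variance decomposition, BestKeeper
    descriptive statistics with index correlation, and the comparative
    delta-Ct method -- together with geometric-mean rank aggregation across
    methods, standard-curve amplification-efficiency estimation, an RNA-seq
    (TPM) candidate pre-selection filter, and a synthetic quantification-cycle
    (Cq) data generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
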