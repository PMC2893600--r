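Package: cshmask
Title: Probe Masking and Expression Analysis for Cross-Species Microarray Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cross-species hybridization (CSH) microarray
    experiments, in which labelled RNA from a target species is hybridized to a
    GeneChip designed for a related reference species. Probes falling in
    inter-species variable (ISV) regions or over single-feature polymorphisms
    (SFPs) give biased signals; the package builds intensity-threshold mask
    files with a replicate-aware retention rule, supports double-masking
    (ISV + SFP), performs RMA-style background correction, quantile
    normalization and median-polish summarization of the retained perfect-match
    probes, selects the operating threshold by jointly optimizing sensitivity
    (commonly-selected gene count) and accuracy (cross-species ratio
    correlation), calls differentially expressed probe sets, and tests
    chromosomal clustering of selected genes by Monte-Carlo genome-bin
    occupancy. A synthetic two-species probe-level data generator with known
    ISV/SFP/differential-expression truth makes the whole pipeline testable
    without array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
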