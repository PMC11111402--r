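Package: geosig
Title: Mutational Signature Extraction, Attribution and Geographic Epidemiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying geographic variation of somatic
    mutational processes in cancer genomes. Classifies somatic mutations into
    the SBS-96/SBS-288, DBS-78 and ID-83 channel schemas and assembles
    per-sample mutational catalogues; extracts de novo signatures by repeated
    Kullback-Leibler non-negative matrix factorization on Poisson-resampled
    catalogues with consensus clustering and stability-based model selection;
    decomposes de novo signatures into a reference catalogue; attributes
    per-sample signature activities by penalized non-negative least squares
    with parametric-bootstrap confidence intervals; and provides the
    epidemiological layer (risk-factor logistic regressions, incidence-rate
    linear regressions, country burden tests, clonal versus subclonal signature
    timing, driver-spectrum enrichment). Ships a synthetic multi-country cohort
    generator with planted ground truth so the whole pipeline is testable
    without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
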