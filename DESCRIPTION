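Package: tmearch
Title: Spatial Heterogeneity Metrics and Immunoarchitecture Classification
    for Simulated Tumor-Immune Cell Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates spatial tumor-immune configurations with a 3-D lattice
    agent-based simulator of anti-PD-1 checkpoint therapy (stem-like,
    progenitor and senescent cancer cells; effector, cytotoxic, exhausted and
    regulatory T cells; a one-compartment pharmacokinetic surrogate with Hill
    blockade; finite-volume cytokine diffusion), quantifies intratumoral
    heterogeneity on pathology-slide-like 2-D regions of interest with four
    spatial metrics (mixing score, average neighbor frequency, spatial
    Shannon entropy, area under the G-cross function) plus the cancer-to-
    immune cell ratio, and classifies tumor-microenvironment
    immunoarchitecture as cold, mixed, or compartmentalized from metric
    values or their percent change under treatment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
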