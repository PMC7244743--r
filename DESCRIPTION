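Package: vnod
Title: Multi-Tissue Constraint-Based Modelling of Legume Nodule Symbiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating multi-tissue holobiont
    metabolic models of symbiotic nitrogen fixation. Integrates a plant and a
    rhizobial genome-scale metabolic reconstruction into a nodulated-plant
    model with shoot, root and five nodule developmental zones, gates each
    zone's reaction space with gene expression calls, and runs flux balance
    analysis experiments: gene and reaction deletions, flux variability and
    robustness analysis, Pareto scans over nitrogen-fixation efficiency and
    nodulation rate, metabolic cost decomposition, and carbon-source-switch
    analysis. Includes a deterministic generator of a miniature, mass- and
    charge-balanced plant/bacterium model pair so the whole pipeline is
    testable without external data, readers and writers for SBML (FBC) and a
    plain tabular model dialect, and a bounded-variable simplex solver for
    the underlying linear programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
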