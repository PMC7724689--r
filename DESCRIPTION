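Package: netpharm
Title: Network Pharmacology Screening for Multi-Herb Remedies
Version: 0.1.0
Authors@R:
    person("netpharm", "maintainers", email = "netpharm@example.org",
           role = c("aut", "cre"))
Description: A local, testable network-pharmacology pipeline for multi-herb
    traditional-medicine formulas: molecular-formula parsing and mass
    computation, pharmacokinetic (ADME) candidate screening with cross-herb
    deduplication, gene-target set normalization, integration and Venn
    overlap analysis, scored protein-protein interaction network
    construction with topological-importance metrics (degree, betweenness,
    closeness, coreness), hypergeometric over-representation analysis with
    Benjamini-Hochberg FDR control, and a synthetic-data generator with
    planted ground truth that replaces live database queries so every stage
    is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
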