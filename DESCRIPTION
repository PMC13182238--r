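Package: mrtier
Title: Multi-Omics Causal-Gene Prioritization with Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing causal genes from GWAS and molecular-QTL
    summary statistics. Implements two-sample Mendelian randomization (Wald
    ratio, inverse-variance weighted, MR-Egger, weighted median) with
    heterogeneity and pleiotropy diagnostics; summary-data-based Mendelian
    randomization (SMR) with the HEIDI heterogeneity-in-dependent-instruments
    test; Bayesian colocalization from Wakefield approximate Bayes factors
    (PP0-PP4); two-step mediation Mendelian randomization with delta-method
    standard errors; and a tiered evidence-integration rule that combines SMR,
    MR and colocalization results into a gene-by-criterion evidence matrix and
    tier labels. A summary-statistic simulator with configurable linkage
    disequilibrium and causal architectures provides ground-truth data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
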