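Package: DomainSifter
Title: Domain-Based Identification and Scoring of Protein Functional Classes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-based identification and characterization of protein
    functional classes (for example RNA-binding proteins) from predicted
    domains. Builds a reference domain set by keyword selection over domain
    annotation tables, ingests domain-search results in BLAST-tabular and
    InterProScan-style dialects, filters predicted domains by optimized
    statistical cut-offs (domain coverage, residue similarity, residue
    identity, E-value, gap fraction), scores candidate sites against their
    reference consensus across chemical, alignment, and composition-distance
    feature categories combined into a Bayesian 0-1 score with empirical
    P-values, and evaluates classifier performance (sensitivity, specificity,
    accuracy, MCC, F-measure, ROC/AUC, cut-off optimization, residue-interval
    overlap). Includes a lightweight position-specific profile scanner and a
    synthetic-data generator so complete analyses run without external
    search engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Classification, Proteomics
RoxygenNote: 7.3.3
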