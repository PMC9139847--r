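Package: proteoforest
Title: Forest Graphical Models and Functional Node Analysis for Tumor Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-tissue tumor proteomics cohorts based
    on forest-structured Gaussian graphical models. Provides preprocessing of
    protein log2-intensity matrices (group-wise valid-value filtering and
    imputation from a downshifted normal distribution), learning of a
    minimal-BIC spanning forest over proteins without prior information,
    decomposition of the forest into branches annotated by hypergeometric
    overrepresentation against gene sets, per-sample functional node
    activities, hierarchical-clustering subtype discovery, multiclass
    significance analysis with permutation-based false discovery rate,
    nearest-centroid classification of external cohorts, and mixed linear
    model contrasts between paired tissue types. Includes a synthetic cohort
    generator emulating block-correlated proteomes with latent tumor subtypes,
    tissue-progression shifts, and intensity-dependent missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
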