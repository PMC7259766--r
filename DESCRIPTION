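Package: cienet
Title: Brain-Regional Coexpression Network Analysis for Chronic Intermittent
    Ethanol Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression and weighted coexpression-network analysis
    of 2x2 (vapor exposure by voluntary drinking) brain expression designs, as
    used in chronic-intermittent-ethanol (CIE) studies. Implements the six
    pairwise treatment-group contrasts and a two-factor interaction model with
    Benjamini-Hochberg FDR control, quantile normalization and ANOVA-based
    probeset selection, soft-thresholded unsigned coexpression networks with
    topological-overlap module detection and module eigengenes, permutation
    validation of module coherence, Spearman correlation of modules and
    probesets with drinking-behavior traits, bootstrap Z statistics for
    treatment-induced module connectivity disruption, and hypergeometric
    gene-list overlap enrichment. A seeded synthetic-data generator emulates
    the study design (four treatment groups, planted coexpression modules,
    drinking-linked eigengenes, group-specific connectivity disruption and
    escalating drinking trajectories) so that every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rlang,
    tibble,
    dplyr,
    tidyr,
    readr,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
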