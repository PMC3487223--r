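Package: dopanet
Title: Reciprocal Fold-Change Meta-Analysis of Dopaminergic Microarray
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transcripts under dopaminergic control from
    two-color cDNA microarray experiments that manipulate dopamine
    signalling in opposite directions (receptor agonists versus
    antagonists or catecholamine depletion).  Provides Generalized
    Procrustes Analysis normalization of two-channel log-intensity
    configurations, one-class Significance Analysis of Microarrays with
    sign-flip permutation q-values, a cross-experiment consensus filter
    that retains genes with reciprocal agonist-versus-blocker fold
    changes and attributes them to D1 or D2 receptors, sub-network
    enrichment analysis over a regulator-target relation table using
    Mann-Whitney U tests, and relative standard-curve qPCR
    quantification with efficiency and linearity quality gates.  A
    synthetic-data generator reproduces the common-reference,
    dye-reversal hybridization design with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
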