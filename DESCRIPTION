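Package: hkgrewire
Title: Housekeeping-Gene Stability, Co-Expression Rewiring and Diagnostic
    Modelling for Case-Control Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying housekeeping genes in case-control
    transcriptomic cohorts. Provides an exon-level housekeeping-gene
    stability filter (ubiquitous detection, low inter-tissue log2-RPKM
    variability, no >= 4-fold outlier tissue, gene-level call via the
    best-supported transcript), two-group differential expression with
    multi-platform intersection and direction consistency, a from-scratch
    weighted co-expression network core (soft-threshold scan with
    scale-free fit, topological overlap, module detection, eigengenes,
    module membership and gene significance, hub selection), a
    differential co-expression "rewiring" statistic that bins per-group
    Pearson correlations into eight fixed intervals and tallies
    control-to-case bin transitions, and an ensemble-averaged neural
    network classifier with standard evaluation metrics. A seeded
    synthetic-data generator plants differential expression, trait-linked
    modules, rewired gene pairs, multi-platform batch structure and
    stable/unstable tissue-exon profiles with full ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
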