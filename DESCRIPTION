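Package: mircascade
Title: Cross-Species miRNA Candidate Selection, Seed-Target Scanning and
    Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("mircascade", "developers", email = "mircascade@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nominating disease-associated
    microRNAs from small RNA sequencing count data: reads-per-million
    quantification over miRNA loci, a cross-dataset and cross-species
    fold-change selection cascade, seed-based 3'-UTR target-site
    scanning in the TargetScan site-class convention, intersection of
    predicted targets with down-regulated genes, locally computed
    hypergeometric gene-set enrichment, and qPCR delta-delta-Ct
    relative quantification with the accompanying group statistics
    (Student t, exact Wilcoxon rank-sum, Bonferroni). Ships seeded
    synthetic-data generators with planted signals so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
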