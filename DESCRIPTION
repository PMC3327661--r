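Package: avimir
Title: Small RNA-Seq miRNA Annotation, Quantification and Cross-Species
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Avimir", "Maintainers", email = "avimir@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for small RNA sequencing surveys of
    microRNAs across related species and developmental stages. Collapses
    adapter-ligated reads, annotates them through a tiered cascade (known
    miRNAs, unannotated star strands, cross-species ortholog rescue with
    seed-preserving mismatches, genome mapping, contaminant classes),
    quantifies detection in reads per million mapped reads, performs
    pairwise differential expression with Fisher's exact test and
    Bonferroni correction, screens hairpins for lineage specificity
    across a genome panel, predicts seed-match targets in 3'UTR sets
    with hypergeometric term enrichment, and generates fully synthetic
    multi-library datasets with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
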