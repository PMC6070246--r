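Package: lncpair
Title: Co-Regulation Analysis of lncRNAs and Neighboring Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying candidate cis-regulatory pairs of long
    noncoding RNAs (lncRNAs) and their closest protein-coding genes (PCGs) from
    multi-group FPKM expression matrices and GTF annotations. Provides presence
    filtering, per-contrast differential expression with a built-in Welch test
    (or imported external results), strand-aware genomic categorization of
    lncRNAs relative to their closest PCG (upstream/UTR/exon/intron/downstream/
    intergenic), lncRNA-PCG pair calling under joint positional and
    differential-expression criteria, multi-contrast Venn partitioning and
    directional pattern classification, and a synthetic-data generator with
    planted ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
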