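Package: canisv
Title: Structural Variation and Mobile-Element Analysis for Canine Pangenome Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing insertion and deletion structural variation in
    multi-sample pangenome graphs of canine genomes. Extracts structural-variant loci
    from a pangenome VCF, classifies the longest allele at each locus into ten
    repeat-composition categories (SINEC, LINE/L1, LTR/ERV, other repeats, low
    complexity, STR, VNTR, mixed, partial, unclassified), analyses allele sharing and
    heterogeneity at dimorphic SINEC and LINE-1 loci, scans full-length LINE-1s for
    intact ORF1p/ORF2p reading frames, extracts and source-traces 3' transductions,
    estimates per-generation mobile-element insertion rates from SNP-calibrated
    divergence, measures permutation-based enrichment of exact short tandem repeats,
    and summarizes segmental-duplication pair tables. Includes a synthetic cohort
    generator that plants dimorphic insertions with target-site duplications on a
    known genealogy so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
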