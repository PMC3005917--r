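Package: editscan
Title: Detection, Quantification and Annotation of RNA Editing Sites from
    Short Expression Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transcriptome-wide discovery of single-base-conversion RNA
    editing sites from short sense-strand expression tags (MPSS-like
    signatures and PARE-like degradome tags). Maps fixed-length tags to
    transcript and pre-miRNA sequences with at most one mismatch, removes
    perfect matchers, aggregates the remaining mismatches into candidate
    sites over the 12 ordered base-conversion patterns, applies
    distinct-read support criteria, and quantifies per-library
    TPM-weighted editing ratios. Downstream annotation covers new start
    and stop codons created inside coding sequences, exon-boundary
    proximity, enrichment of sites near the CDS/3'UTR translation border,
    100-nt sequence-context information profiles, GO term enrichment of
    edited genes, tissue clustering of editing ratios, and secondary
    structure comparison of edited pre-miRNA hairpins. A synthetic-data
    generator emulates the tag libraries so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    withr,
    generics,
    jsonlite,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
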