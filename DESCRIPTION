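Package: mavemap
Title: Map Multiplexed Assay of Variant Effect Score Sets to Reference Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lifting variants from multiplexed assays of variant
    effect (MAVE) score sets, described on assay-specific target sequences,
    onto reference genome and protein sequences. Provides MAVE-HGVS parsing,
    a content-addressed sequence store with truncated SHA-512 digests, a
    seed-chain-extend local aligner producing block-based (PSL-style) hits,
    MANE-tiered transcript selection with protein residue offsets, allele
    normalization to full justification with computed identifiers,
    cis-phased blocks, pre-/post-mapped variant pairing with concordance
    classification, concordance summaries, per-residue score aggregation,
    percentile outlier calling, and BED/JSON export. Includes a deterministic
    synthetic fixture generator emulating codon-optimized targets, minigene
    inserts, heavily mutagenized targets, truncated targets and
    exon-spanning edits, with machine-checkable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
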