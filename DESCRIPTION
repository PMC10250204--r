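Package: aiso
Title: Adjacent Introns' Splicing Order from Short- and Long-Read RNA-seq
Version: 0.1.0
Authors@R: person("AISO", "Maintainers", email = "aiso@example.org", role = c("aut", "cre"))
Description: Quantifies the order in which the two introns flanking an
    internal exon are spliced (adjacent introns' splicing order, AISO)
    from spliced RNA-seq alignments. Provides a GTF-driven exon-table
    extractor that clusters overlapping exons of a gene into exon
    entities and classifies exon types, a fragment classifier that
    assigns reads or read pairs to upstream-first/downstream-first/
    both-spliced/both-unspliced configurations with fuzzy splice-site
    matching and effective-intron-length debiasing, an optional
    truncation bias correction for long reads, per-exon Fupfi/PSI/PIR
    metrics, cross-sample consistency statistics, and a read simulator
    that generates annotations, partially spliced molecules and aligned
    reads with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
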