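Package: mipepscan
Title: Small-ORF Surveys, Ribo-Seq Peptide Matching and miPEP Annotation
    in Primary microRNA Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether primary microRNA transcripts
    (pri-miRs) harbour translatable short open reading frames (sORFs) and
    for characterising the micropeptides (miPEPs) they may encode.
    Provides an ATG-initiated ORF scanner with per-kilobase density
    comparisons across RNA classes, three-frame translation and exact
    matching of ribosome-profiling-derived sORF peptides, annotation of
    candidate miORFs upstream of the pre-miR hairpin (alternative in-frame
    starts, start-codon context scoring, point-variant consequences),
    TMM-normalised negative-binomial differential-expression calling with
    two-condition Venn partitioning, Mendelian progeny expectations under
    balancer lethality with goodness-of-fit tests, and a seeded synthetic
    data generator that plants ground-truth structure in every input type
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
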