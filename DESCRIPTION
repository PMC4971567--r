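Package: clinexome
Title: Clinical Exome Coverage QC, Variant Flagging and Trio De Novo Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-alignment, post-calling stages of a clinical exome pipeline:
    per-base coverage and quality metrics over BED targets with
    transcript-coordinate (c.) annotation of failing subregions, Platypus-style
    VCF post-processing with high/low quality flags based on QUAL and the
    variant allele fraction, simplified variant-consequence classification with
    most-5' and most-3' indel representations, proband-parent trio de novo
    candidate identification, default-transcript selection with CCDS
    preference, and a deterministic synthetic-fixture generator (reference
    FASTA, transcript database, alignments, variant calls, trios) for testing
    the whole pipeline without access to controlled human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
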