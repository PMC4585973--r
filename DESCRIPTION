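Package: goldset
Title: Gold-Standard Variant Truth Sets and Structural-Variant Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-confidence ("gold") variant truth sets for a single
    genome from multi-platform, multi-caller evidence. Small variants are
    admitted by a two-criterion consensus (called on every platform, and by at
    least two distinct callers); candidate structural variants (deletions and
    insertions >= 50 bp) are extracted from split and gapped long-read
    alignments, merged across sources, and validated by breakpoint-junction
    read mapping, discordant read-pair analysis, and overlap with a
    known-variant database, then tiered Gold/Pass/Notval by the number of
    independent validation sources. Alignments are further distilled into
    "no structural variant regions" (NSVR) -- intervals covered only by
    multiple uniquely-mapped, end-to-end, low-edit-distance reads -- which
    anchor an NSVR-based false-discovery-rate estimate. An evaluation module
    matches caller output against a gold set and reports TP, TPR, NSVR-FP,
    NSVR-FDR and F1, and a seeded simulator generates reference contigs,
    diploid donors with implanted variants, aligned reads and noisy per-caller
    callsets so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
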