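Package: teilr
Title: Non-Reference Transposable Element Insertion Calling from Long Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects non-reference transposable element insertions (TEIs) in
    long-read whole-genome alignments. Insertion CIGAR operations and
    soft-clipped read ends are extracted from a coordinate-sorted BAM/CRAM,
    breakpoint positions are clustered per contig with a one-dimensional
    DBSCAN, candidate sequences are realigned against a user-supplied TE
    consensus library (minimap2, with a built-in Smith-Waterman fallback),
    and clusters with sufficient same-family read support are refined to a
    consensus breakpoint, genotyped haplotype-aware from read phasing tags,
    and written as symbolic INS:ME records in a VCF 4.2 file. A seeded
    simulation module generates diploid genomes with planted TE insertions,
    noisy long reads at configurable coverage, and truth sets, and an
    evaluator scores calls against truth by family and breakpoint window.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: minimap2 (optional; a built-in aligner is used when absent)
Config/testthat/edition: 3
biocViews: StructuralVariation, VariantDetection, Sequencing, Alignment
RoxygenNote: 7.3.3
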