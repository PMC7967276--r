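Package: divtss
Title: Refining Transcription Start Sites of Divergently Transcribed
    Bacterial ncRNAs from 5'-End RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for mapping and refining transcription
    start sites (TSSs) of bacterial non-coding RNAs from 5'-end-specific
    RNA-seq. Implements adapter trimming and minimum-length read filtering,
    perfect-match selection of alignments by SAM XM/NM tags, strand-specific
    5'-end pileups, per-replicate depth normalization by the ratio of the
    group-average to the per-replicate perfect-match read count, TSS peak
    calling with primary/secondary ranking and signed shifts relative to an
    annotation, classification of ncRNA/neighbor-gene arrangements
    (codirected, divergent, 5'-overlapping antisense), inter-TSS distance
    summaries for divergent pairs, and a screen of intergenic REP (repetitive
    extragenic palindromic) elements for divergent transcription, poly-T
    tracks and candidate intrinsic terminator hairpins. Ships a deterministic
    synthetic-data generator (genome, GFF3 annotation, FASTQ reads, SAM
    alignments, truth tables) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    GenomicAlignments,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
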