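Package: ervchimera
Title: Detection of ERV/LTR-Anchored Chimeric Transcription from Stranded
    Paired-End RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers chimeric transcription anchored at endogenous
    retroviral (ERV) long terminal repeats from stranded paired-end RNA-seq.
    Read pairs in which exactly one mate's prefix matches an LTR U3 consensus
    are selected, the free mates are mapped uniquely and splice-aware against
    the genome, and the alignments are gap-merged into repeat-linked chimeric
    positions. Companion machinery builds strand-specific coverage tracks,
    segments them into transcribed patches and (bidirectional) loci, links
    chimeric splice junctions to repeats, classifies the chromatin state of
    positions from H3K4me3/H3K27ac peaks and promoter segments, attaches CAGE
    TSS evidence, and compares activation across samples. A deterministic
    synthetic-data module generates toy genomes, planted repeat copies,
    LTR-initiated transcriptomes, stranded read pairs and matched regulatory
    tracks with a truth table, so the whole pipeline runs and is validated at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
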