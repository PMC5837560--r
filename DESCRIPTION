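Package: cutscreen
Title: Screening Tandem lncRNA-Gene Pairs for Termination-Dependent
    Transcriptional Interference in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reanalysis pipeline for tandem CUT-gene architecture in
    Saccharomyces cerevisiae. Selects cryptic unstable transcripts (CUTs)
    located upstream in tandem of a protein-coding gene with a clean gap
    interval, quantifies promoter directionality from NET-seq 5' coverage,
    computes an Nrd1-depletion read-through index from Pol II PAR-CLIP
    tracks, detects PAR-CLIP crosslink sites from pileup records and
    derives 4sU-normalized Nrd1/Nab3 occupancy, counts NNS-pathway RNA
    binding motifs, and quantifies ChIP-qPCR enrichment and gated
    flow-cytometry fluorescence. A synthetic-data module generates
    annotations, stranded coverage, pileups, qPCR and flow fixtures with
    known ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
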