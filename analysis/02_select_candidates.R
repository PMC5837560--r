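#!/usr/bin/env Rscript
# Stage 2: the candidate funnel. CUTs overlapping any other transcription
# unit are removed; for the survivors the nearest same-strand downstream
# gene is found; pairs are kept when the gap interval (CUT 3' end to gene
# TSS) is 100-1500 bp long and clean of other units on either strand.

suppressPackageStartupMessages(library(cutscreen))

fix <- file.path("results", "fixtures")
genome <- read_genome(file.path(fix, "genome.tsv"))
cuts <- read_annotations(file.path(fix, "cuts.bed"), "CUT", genome)
suts <- read_annotations(file.path(fix, "suts.bed"), "SUT", genome)
genes <- read_annotations(file.path(fix, "genes.bed"), "gene", genome)
all_units <- c(cuts, suts, genes)

kept <- remove_overlapping_cuts(cuts, all_units)
pairs <- select_candidate_pairs(cuts, genes, all_units)

cat(length(cuts), "CUTs loaded;", length(kept),
    "after overlap removal;", nrow(pairs), "final tandem pairs\n")

truth <- utils::read.table(file.path(fix, "truth.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
expected <- truth$cut_id[truth$valid]
cat("ground truth check:", length(intersect(pairs$cut_id, expected)), "of",
    length(expected), "planted pairs recovered,",
    length(setdiff(pairs$cut_id, expected)), "spurious\n")

utils::write.table(pairs, file.path("results", "candidate_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/candidate_pairs.tsv\n")
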