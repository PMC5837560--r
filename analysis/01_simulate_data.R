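#!/usr/bin/env Rscript
# Stage 1: materialize a synthetic study dataset with known ground truth.
#
# Generates a two-chromosome toy genome carrying tandem CUT-gene cassettes
# (plus overlap, interloper and gap-length decoys), NET-seq and Pol II
# PAR-CLIP 5'-tag tracks, a 4sU-seq nascent track, PAR-CLIP pileups with
# planted T-to-C / A-to-G conversion sites, and qPCR/flow assay tables.
# Everything downstream reads these files through the package's readers.

suppressPackageStartupMessages(library(cutscreen))

seed <- 1L
out <- file.path("results", "fixtures")

sim <- simulate_annotation(n_valid = 10, n_overlap_decoys = 3,
                           n_interloper_decoys = 3, n_gap_decoys = 3,
                           seed = seed)
paths <- write_simulation_fixtures(sim, out)

# genome sequence for the motif stage
gseq <- simulate_genome_sequence(sim)
Biostrings::writeXStringSet(gseq, file.path(out, "genome.fa"))

utils::write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("simulated", nrow(sim$truth), "CUT-gene cassettes on",
    length(sim$genome), "chromosomes (seed", seed, "):\n")
print(table(sim$truth$type))
cat("wrote", length(list.files(out)), "files under", out, "\n")
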