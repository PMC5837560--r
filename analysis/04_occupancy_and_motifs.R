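#!/usr/bin/env Rscript
# Stage 4: NNS targeting of the candidate CUTs. Crosslink sites are called
# from PAR-CLIP pileups (T-to-C forward / A-to-G reverse conversions),
# scaled to one million tags, divided by the 51-bp-smoothed 4sU-seq
# nascent signal (pseudocount 0.1 at zero-coverage positions), and summed
# over each CUT; Nrd1/Nab3 consensus motifs are counted in each CUT's RNA.

suppressPackageStartupMessages(library(cutscreen))

fix <- file.path("results", "fixtures")
genome <- read_genome(file.path(fix, "genome.tsv"))
pairs <- utils::read.table(file.path("results", "candidate_pairs.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)

pileups <- read_pileup(file.path(fix, "parclip_pileup.tsv"))
sites <- detect_crosslink_sites(pileups)
cat("crosslink sites called:", nrow(sites), "\n")

nascent <- read_coverage(file.path(fix, "nascent_4su_plus.bedgraph"),
                         file.path(fix, "nascent_4su_minus.bedgraph"),
                         genome)
occ <- normalized_occupancy(crosslink_track(sites, genome),
                            smooth_nascent(nascent))
pairs$nrd1_occupancy <- vapply(seq_len(nrow(pairs)), function(i) {
  p <- pairs[i, ]
  occupancy_over_interval(occ, genomic_interval(p$chrom, p$cut_start,
                                                p$cut_end, p$strand))
}, 0)

gseq <- Biostrings::readDNAStringSet(file.path(fix, "genome.fa"))
names(gseq) <- sub("\\s.*$", "", names(gseq))
pairs <- add_motif_counts(pairs, gseq)

cat(sprintf("mean 4sU-normalized occupancy per CUT: %.0f\n",
            mean(pairs$nrd1_occupancy)))
cat(sprintf("mean motif counts per CUT: Nrd1 %.1f, Nab3 %.1f\n",
            mean(pairs$nrd1_motif_count), mean(pairs$nab3_motif_count)))

utils::write.table(pairs, file.path("results", "candidate_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("updated results/candidate_pairs.tsv with occupancy and motif columns\n")
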