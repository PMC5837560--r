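#!/usr/bin/env Rscript
# Stage 3: per-pair transcription statistics. Promoter directionality from
# NET-seq (coding-strand signal over the gene's first 100 bp against
# divergent-strand signal over the gap's last 100 bp, pseudocount 0.25)
# and the Nrd1-depletion read-through index from the Pol II PAR-CLIP
# treatment/control track pair, both normalized to one million tags.

suppressPackageStartupMessages(library(cutscreen))

fix <- file.path("results", "fixtures")
genome <- read_genome(file.path(fix, "genome.tsv"))
pairs <- utils::read.table(file.path("results", "candidate_pairs.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)

netseq <- normalize_cpm(read_coverage(
  file.path(fix, "netseq_plus.bedgraph"),
  file.path(fix, "netseq_minus.bedgraph"), genome))
trt <- normalize_cpm(read_coverage(
  file.path(fix, "polii_parclip_nrd1_depleted_plus.bedgraph"),
  file.path(fix, "polii_parclip_nrd1_depleted_minus.bedgraph"), genome))
ctl <- normalize_cpm(read_coverage(
  file.path(fix, "polii_parclip_control_plus.bedgraph"),
  file.path(fix, "polii_parclip_control_minus.bedgraph"), genome))

pairs <- add_transcription_metrics(pairs, netseq, trt, ctl)

truth <- utils::read.table(file.path(fix, "truth.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
tru <- truth[match(pairs$cut_id, truth$cut_id), ]
expected_rt <- (1 - tru$theta * (1 - tru$delta)) / (1 - tru$theta)

cat(sprintf("directionality index: median %.1f (range %.1f-%.1f)\n",
            stats::median(pairs$directionality_index),
            min(pairs$directionality_index),
            max(pairs$directionality_index)))
cat(sprintf(
  "read-through index vs truth expectation: mean ratio %.3f (n = %d)\n",
  mean(pairs$readthrough_index / expected_rt), nrow(pairs)))
cat(sprintf("rank correlation with expected read-through: %.3f\n",
            stats::cor(pairs$readthrough_index, expected_rt,
                       method = "spearman")))

utils::write.table(pairs, file.path("results", "candidate_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("updated results/candidate_pairs.tsv with metric columns\n")
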