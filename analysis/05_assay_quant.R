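#!/usr/bin/env Rscript
# Stage 5: bench-assay quantification. ChIP-qPCR %IP with the delta-CT
# formula and dilution correction (input 1/100, IP 1/50), normalized to a
# household locus; flow-cytometry gating (time trim, +-25% median SSC
# band, 500-event minimum) with background subtraction and normalization
# to the co-assayed reference strain.

suppressPackageStartupMessages(library(cutscreen))

fix <- file.path("results", "fixtures")

## ChIP-qPCR
qpcr <- read_qpcr(file.path(fix, "chip_qpcr_ct.csv"))
qpcr$pct_ip <- percent_ip(qpcr$ct_input, qpcr$ct_ip,
                          qpcr$dilution_input, qpcr$dilution_ip)
by_locus <- stats::aggregate(pct_ip ~ locus, qpcr, mean)
ref <- by_locus$pct_ip[by_locus$locus == "ACT1"]
by_locus$relative_to_act1 <- relative_enrichment(by_locus$pct_ip, ref)
cat("ChIP-qPCR enrichment (mean of", max(qpcr$replicate), "replicates):\n")
print(by_locus, row.names = FALSE)

prom <- qpcr$pct_ip[qpcr$locus == "ATP16_promoter"]
body <- qpcr$pct_ip[qpcr$locus == "ATP16_body"]
rs <- replicate_summary(prom, body)
cat(sprintf("promoter vs body: %.4f +- %.4f against %.4f +- %.4f, p = %.3g %s\n",
            rs$mean, rs$sem, rs$comparison_mean, rs$comparison_sem,
            rs$p_value, rs$stars))

## Flow cytometry
ev <- read_flow_events(file.path(fix, "flow_events.csv"))
wells <- lapply(split(ev, ev$strain), gate_events)
for (s in names(wells))
  cat(sprintf("strain %-10s %5d events -> %4d gated%s\n", s,
              wells[[s]]$n_input, wells[[s]]$n_gated,
              if (wells[[s]]$excluded) " (EXCLUDED)" else ""))
yfp <- fluorescence_summary(wells, "background", "reference", "yfp")
mch <- fluorescence_summary(wells, "background", "reference", "mcherry")
flow_tab <- data.frame(strain = names(yfp), yfp = unname(yfp),
                       mcherry = unname(mch))
cat("normalized fluorescence:\n")
print(flow_tab, row.names = FALSE)

utils::write.table(by_locus, file.path("results", "chip_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(flow_tab, file.path("results", "flow_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/chip_enrichment.tsv and results/flow_summary.tsv\n")
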