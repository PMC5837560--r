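# cutscreen

Screening tandem lncRNA–gene architecture in budding yeast for
termination-dependent transcriptional interference.

Many yeast promoters fire bidirectionally, so a cryptic unstable
transcript (CUT) can sit upstream, in tandem, of a protein-coding gene.
When the Nrd1–Nab3–Sen1 (NNS) pathway terminates the CUT efficiently, the
downstream promoter is insulated; when termination fails, Pol II reads
through the promoter and represses it by transcriptional interference.
`cutscreen` is the computational pipeline of a genome-wide screen for
this architecture, for researchers reanalyzing yeast nascent-transcription
data: it selects CUT–gene candidate pairs by genomic configuration and
scores them from NET-seq, Pol II PAR-CLIP and Nrd1/Nab3 PAR-CLIP +
4sU-seq data, and it quantifies the validation assays (ChIP-qPCR, flow
cytometry).

## Core statistics

For a CUT with 3′ end at the start of a *gap interval* of length d
(100 ≤ d ≤ 1500 bp, no other unit in the gap on either strand) ending at
the downstream gene's TSS:

- **Directionality index** (NET-seq 5′ tags):
  `coding / (divergent + 0.25)`, with *coding* the signal over the
  gene's first 100 bp on the coding strand and *divergent* the signal
  over the gap's last 100 bp on the opposite strand.
- **Read-through index** (Pol II PAR-CLIP, Nrd1 depletion T vs control
  C, tracks normalized to 10⁶ tags, CUT-strand signal):
  `(gap_T / cut_T) / (gap_C / cut_C)` — values > 1 indicate
  Nrd1-dependent termination failure.
- **Normalized NNS occupancy**: PAR-CLIP crosslink sites (T→C forward /
  A→G reverse conversions, explicit thresholds) scaled to 10⁶ tags,
  divided by the 51-bp-smoothed 4sU-seq signal (pseudocount 0.1 at
  zero-coverage positions), summed over the CUT.
- **NNS motif counts**: overlapping occurrences of Nrd1 (GUAA, GUAG)
  and Nab3 (UCUU, CUUG) motifs in the CUT RNA.
- **Assays**: ChIP-qPCR
  `%IP = 2^(CT_input − CT_IP) × (dil_input / dil_IP)`; flow wells gated
  by time trim (first ⅓, last ⅑), ±25 % median-SSC band and a 500-event
  minimum, then background-subtracted and normalized to the reference
  strain; replicate summaries as mean ± s.e.m. with two-tailed unpaired
  Student's t-tests.

A synthetic-data module generates annotations with decoys, Poisson tag
tracks with per-CUT termination efficiency θ and depletion effect δ,
pileups with planted conversion sites, and qPCR/flow tables — with known
ground truth, so the whole pipeline is testable offline.

## Worked example

The numbered drivers under `analysis/` run the screen end to end on a
simulated dataset (written under `results/`):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_select_candidates.R
Rscript analysis/03_transcription_metrics.R
Rscript analysis/04_occupancy_and_motifs.R
Rscript analysis/05_assay_quant.R
```

Output of stages 2 and 3 on the default seed:

```
19 CUTs loaded; 16 after overlap removal; 10 final tandem pairs
ground truth check: 10 of 10 planted pairs recovered, 0 spurious
directionality index: median 5.2 (range 4.4-6.4)
read-through index vs truth expectation: mean ratio 1.066 (n = 10)
rank correlation with expected read-through: 0.830
```

The funnel removes the 3 planted overlap decoys (16 left of 19) and the
gap-length/interloper decoys, recovering exactly the 10 planted pairs.
The per-pair read-through index averages within ~7 % of its expectation
(1 − θ(1 − δ))/(1 − θ) and ranks pairs by depletion effect. The same
run appends occupancy and motif columns and prints the assay tables,
e.g. gated flow fluorescence `circuitII yfp 0.40` against the planted
net ratio 16/40 = 0.40.

Equivalent calls in R:

```r
library(cutscreen)
sim   <- simulate_annotation(n_valid = 10, seed = 1)
pairs <- select_candidate_pairs(sim$cuts, sim$genes, sim$annotation)
net   <- normalize_cpm(simulate_netseq(sim))
pairs <- add_transcription_metrics(pairs, netseq = net)
```

`run_screen(pipeline_config(...))` performs the same stages from files
(BED6, stranded bedGraph/Wig, pileup TSV) and writes the candidate table
plus a manifest with constants, input checksums and the seed.

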