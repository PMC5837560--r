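---
title: "Screening tandem CUT-gene architecture for termination-dependent interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tandem CUT-gene architecture for termination-dependent interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutscreen)
```

## The biological question

Budding yeast promoters are pervasively bidirectional. A cryptic unstable
transcript (CUT) initiated divergently from one gene's promoter can sit
immediately upstream, in tandem, of a second gene. If the CUT is
terminated efficiently by the Nrd1--Nab3--Sen1 (NNS) pathway, the
downstream promoter is insulated; if termination fails, RNA polymerase II
reads through the downstream promoter and can repress it by
transcriptional interference (TI) — elongation-associated chromatin marks
(H3K36me3) accumulate over the promoter and block initiation.

`cutscreen` implements the computational side of a genome-wide screen for
this architecture: it selects CUT--gene pairs by genomic configuration,
and scores each pair with statistics derived from nascent-transcription
datasets (NET-seq, Pol II PAR-CLIP under Nrd1 depletion, Nrd1/Nab3
PAR-CLIP with 4sU-seq), plus the bench readouts used to validate
candidates (ChIP-qPCR, flow cytometry of fluorescent reporter circuits).

## The screen, stage by stage

**Candidate selection.** From annotated CUTs, SUTs and genes (BED6,
0-based half-open, sacCer3-style coordinates):

1. remove every CUT that overlaps (shares at least one base with) any
   other transcription unit, on either strand;
2. for each surviving CUT find the nearest downstream gene on the same
   strand — downstream means the gene's transcription start site (TSS)
   lies strictly beyond the CUT's 3' end in the direction of
   transcription;
3. keep the pair when the *gap interval* (CUT 3' end to gene TSS) is
   100--1500 bp long, inclusive on both ends, and contains no other
   transcription unit on either strand.

Strand conventions for half-open intervals: a plus-strand unit's TSS is
its `start` and its 3' end its `end`; mirrored on the minus strand.
Nearest-gene ties break deterministically by smaller start coordinate
then lexicographic id. The distance filter is inclusive on both bounds
(100 ≤ d ≤ 1500), and both bounds are exposed in `selection_config()`. The overlap test of step 1
is either-strand by default (`stranded_overlap = FALSE`) to match the
explicitly either-strand gap test; a same-strand variant is a flag.

**Promoter directionality (NET-seq).** NET-seq 5'-tag coverage marks Pol
II positions. For each pair,

- *coding* signal: the sum over the first `window` (default 100) bp of
  the gene on the coding strand;
- *divergent* signal: the sum over the last `window` bp of the gap on the
  opposite strand (the divergent direction of the gene's promoter);
- index = coding / (divergent + 0.25).

The 0.25 pseudocount guards the division against empty divergent
windows; the index is therefore monotone increasing in coding signal and
decreasing in divergent signal. Gaps or genes shorter than the window
truncate it, with a message. A high index flags a unidirectional
downstream promoter — the configuration most exposed to read-through
interference.

**Read-through index (Pol II PAR-CLIP).** With a depletion (Nrd1-AA +
rapamycin) track T and a control track C, both normalized to one million
tags, and signals measured on the CUT strand:

index = (gap_T / cut_T) / (gap_C / cut_C).

Values above 1 mean Nrd1 depletion shifted polymerase from the CUT body
into the gap — termination of that CUT depends on Nrd1. The statistic is
invariant to global rescaling of either track, so the normalization
target cancels; it is computed per pair and fails loudly (naming the
pair) on a zero denominator. No pseudocount is applied by
default — silently added mass would blur the statistic's meaning; a
`pseudocount` argument is available where sparse data require it. The gap signal is strand-restricted by
default (`gap_strand = "same"`); a both-strand variant is a flag.

**Crosslink sites and normalized occupancy (Nrd1/Nab3 PAR-CLIP +
4sU-seq).** 4-thiouridine crosslinking leaves diagnostic T-to-C
conversions in plus-strand reads and A-to-G in minus-strand reads. Variant-caller-based site calling hides its decision rule in caller
settings; this package instead applies an explicit, reproducible rule,
configurable in `occupancy_config()`: a site requires reference base T (plus) or A
(minus), at least `min_converted_reads` (2) converted reads, depth at
least `min_total_reads` (10), and conversion fraction at least
`min_conversion_fraction` (0.01). These defaults are package design decisions. Site values (converted-read counts) are scaled to
one million tags.

To correct binding signal for the transcription level of the underlying
locus, the 4sU-seq track is smoothed with a 51-bp centred sliding mean
in which zero-coverage positions are replaced by 0.1 *inside the window*
(the pseudocount substitutes for zeros; it is not added to nonzero
positions), windows truncating
at chromosome ends rather than padding. The smoothed track is strictly
positive, so the per-position quotient PAR-CLIP / smoothed-4sU is always
defined where there is signal. Occupancy over a CUT is the *sum* of the
quotient track across the CUT body — the sum preserves site-count
information — and `aggregate = "mean"` exists for length-matched
comparisons.

**NNS motifs.** Nrd1 recognizes GUAA/GUAG, Nab3 UCUU/CUUG in nascent
RNA. `motif_set()` takes these literature-standard tetramers as
configurable defaults.
Occurrences are counted overlapping (binding sites are positional, not
tiling) in the strand-resolved RNA of each CUT.

**Bench assays.** ChIP-qPCR enrichment is
%IP = 2^(CT_input − CT_IP) × (dilution_input / dilution_IP), with
default dilutions 1/100 (input) and 1/50 (IP); ratios of %IP give
mark/H3 and household-gene normalizations. Flow-cytometry wells are
gated by (i) dropping the first floor(n/3) and last floor(n/9) of events
in time (unstable flow at run edges; floors, for determinism), (ii) keeping events within ±25% of the
survivors' median side scatter (the gate is computed after the time
trim — the trim exists to remove unstable flow, so it belongs first;
gating before trimming is a flag-level change away), (iii) excluding wells with fewer than 500 gated events — an
exclusion verdict, not an error. Fluorescence is background-subtracted
(arithmetic mean of the no-reporter strain) and normalized to the
co-assayed wild-type reference, which therefore scores exactly 1.
Replicate summaries report mean ± s.e.m. and a two-tailed unpaired
Student's t-test (pooled variance by default) with stars at 0.05 / 0.01
/ 0.001.

## The synthetic data generator

Real accessions cannot be bundled, so `simulate_annotation()` and its
companions generate a fully specified study: a toy genome (two 200-kb
chromosomes — large enough for ~20 well-separated cassettes, small
enough that a full pipeline run takes seconds) carrying tandem CUT→gene
cassettes with gap lengths drawn inside the selection range, plus three
decoy classes that each violate exactly one criterion: a unit overlapping
the CUT, an interloping SUT inside the gap, or a gap length outside
100--1500 bp. The truth table records which CUTs a correct screen must
recover.

Coverage is Poisson per position — no read-length structure, because
every downstream statistic consumes 5'-tag counts only. Each CUT carries
a termination efficiency θ and a depletion effect δ
(θ_depleted = θ(1−δ)): the control PAR-CLIP gap rate is λ(1−θ), the
depleted gap rate λ(1−θ(1−δ)), so the expected read-through index is
(1−θ(1−δ))/(1−θ) and is monotone in δ. Defaults are θ ~ U(0.6, 0.95)
(efficient but imperfect NNS termination), δ = 0.5, CUT rate 1 tag/bp,
gene rate 5 tags/bp (genes are transcribed several-fold above CUTs),
divergent fraction 0.2 over 200 bp upstream of each TSS. Pileups plant
conversion sites at known positions (depth 50, conversion probability
0.5 by default) with the correct reference base and read strand, plus
non-T/non-A reference positions as false-positive bait. qPCR tables
invert the %IP formula with Gaussian CT noise (sd 0.1 cycles);
flow wells plant log-normal SSC (sdlog 0.08), a 2% debris fraction at
extreme SSC, and a 10% early-time drift population with 1.5× shifted
fluorescence — entirely inside the trimmed third, so gating removes it.

What the generator does *not* emulate: mappability artifacts, PCR
duplicates, sequencing errors in the conversion counts, non-Poisson
overdispersion, correlated replicate structure, or any sequence
dependence of crosslinking. Passing tests therefore demonstrate that the
statistics recover planted parameters under their own model assumptions,
not that the thresholds are optimal on real libraries.

## Numerical choices

- All internal coordinates are 0-based half-open; Wig input (1-based) is
  converted on read. Minus-strand bedGraph values are stored non-negated
  — strand is structural, never a sign — and difference tracks
  (`subtract_tracks()`) are the one place negative values are legal.
- `write_coverage()` emits run-length-merged bedGraph with `%.17g`
  values, so a write/read round trip reproduces every position exactly.
- The sliding-window smoother assigns windows lying entirely within one
  constant run the run value directly, making constant regions and
  all-zero chromosomes exact fixed points (0.1 for zeros) instead of
  accumulating cumulative-sum round-off.
- Normalization mass counts both strands jointly: "one million tags"
  refers to library size, not per-strand totals.
- Alignment filtering drops MAPQ ≤ 10 (boundary dropped), unmapped
  reads, reads missing MAPQ (treated as 0, with a message), and reads
  overlapping rRNA/tRNA/snRNA/snoRNA exclusion regions by ≥ 1 bp on
  either strand. Spliced reads contribute a single 5' tag from the full
  alignment span, taken at the aligned (clipped) start. Duplicates are
  retained: no deduplication was specified.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
screens of 10 planted pairs plus 9 decoys on 2 × 200 kb, 200 randomized
mini-genomes for the selection oracle comparison, 20 replicates per
depletion condition for the read-through monotonicity check, 105 planted
crosslink sites for the recall check, 100 qPCR replicates and 3000-event
flow wells for parameter recovery. These sizes were chosen so the whole
workflow re-runs in about a minute while keeping Monte-Carlo margins
(3σ, 5% bias bounds) comfortably away from their thresholds.

## Known limitations

- The published-scale funnel (925 CUTs → 238 → 68 pairs) needs the
  published coordinate tables, which must be fetched separately; the
  test encoding that expectation fails until they are placed under
  `tests/testthat/published-data/`.
- Occupancy-per-CUT is a sum; comparisons between CUTs of very different
  lengths may prefer the mean variant.
- The conversion-site caller is threshold-based; it does not model
  sequencing error or strand-specific artifacts, and its defaults are
  package decisions that should be tuned per dataset.
- BigWig, BAM random access and assembly liftover are out of scope; the
  pipeline consumes aligned reads or pre-made tracks in plain-text
  formats.
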