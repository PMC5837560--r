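# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the package
# implementations they check.

annot_df <- function(gr) {
  data.frame(id = GenomicRanges::mcols(gr)$id,
             class = GenomicRanges::mcols(gr)$class,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# O(n^2) reference implementation of the candidate screen on plain
# data.frames: per-CUT exhaustive overlap scan, exhaustive downstream
# gene scan with the same tie-break, and exhaustive gap-cleanliness scan.
oracle_select_pairs <- function(annot, config = selection_config()) {
  df <- annot_df(annot)
  cuts <- df[df$class == "CUT", , drop = FALSE]
  genes <- df[df$class == "gene", , drop = FALSE]
  hits <- function(sub, chrom, s, e)
    nrow(sub) > 0L && any(sub$chrom == chrom &
                            pmax(sub$start, s) < pmin(sub$end, e))
  rows <- list()
  for (i in seq_len(nrow(cuts))) {
    cut <- cuts[i, ]
    if (hits(df[df$id != cut$id, ], cut$chrom, cut$start, cut$end)) next
    g <- genes[genes$chrom == cut$chrom & genes$strand == cut$strand, ,
               drop = FALSE]
    if (nrow(g) == 0L) next
    d <- if (cut$strand == "+") g$start - cut$end else cut$start - g$end
    keep <- d > 0L
    g <- g[keep, , drop = FALSE]; d <- d[keep]
    if (length(d) == 0L) next
    ord <- order(d, g$start, g$id)
    g <- g[ord[1L], ]; d <- d[ord[1L]]
    if (d < config$min_gap || d > config$max_gap) next
    gap <- if (cut$strand == "+") c(cut$end, g$start) else c(g$end, cut$start)
    if (hits(df[!df$id %in% c(cut$id, g$id), ], cut$chrom, gap[1L],
             gap[2L])) next
    rows[[length(rows) + 1L]] <- data.frame(
      cut_id = cut$id, chrom = cut$chrom, cut_start = cut$start,
      cut_end = cut$end, strand = cut$strand, gene_id = g$id,
      gene_start = g$start, gene_end = g$end, gap_start = gap[1L],
      gap_end = gap[2L], distance = as.integer(d), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cut_id = character(0), chrom = character(0), cut_start = integer(0),
    cut_end = integer(0), strand = character(0), gene_id = character(0),
    gene_start = integer(0), gene_end = integer(0), gap_start = integer(0),
    gap_end = integer(0), distance = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$gap_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unstructured random annotation (overlaps arise naturally) for
# property-style comparisons against the oracle.
random_annotation <- function(n_units = 15L,
                              genome = c(rA = 20000L, rB = 20000L)) {
  cls <- sample(c("CUT", "gene", "SUT"), n_units, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
  chrom <- sample(names(genome), n_units, replace = TRUE)
  start <- vapply(chrom, function(ch)
    sample.int(genome[[ch]] - 3000L, 1L), 0L)
  len <- sample(100:2000, n_units, replace = TRUE)
  annotation_set(sprintf("u%03d", seq_len(n_units)), cls, chrom, start,
                 start + len, sample(c("+", "-"), n_units, replace = TRUE),
                 genome)
}

# Build a coverage track from a data.frame of (chrom, pos, strand, value)
# point signals.
track_from_positions <- function(df, genome, allow_negative = FALSE) {
  build <- function(s) {
    sel <- df$strand == s
    GenomicRanges::GRanges(df$chrom[sel],
                           IRanges::IRanges(df$pos[sel] + 1L, width = 1L),
                           score = df$value[sel])
  }
  coverage_track(build("+"), build("-"), genome,
                 allow_negative = allow_negative)
}

dense_values <- function(track, chrom, strand) {
  as.numeric(if (strand == "+") track$plus[[chrom]] else
    track$minus[[chrom]])
}

# Position-by-position motif scan (overlapping occurrences).
scan_motif <- function(seq, motif) {
  n <- nchar(seq); w <- nchar(motif)
  if (w > n) return(0L)
  sum(vapply(seq_len(n - w + 1L), function(i)
    substr(seq, i, i + w - 1L) == motif, TRUE))
}

# Per-record reference implementation of crosslink-site calling.
oracle_crosslink_sites <- function(pileups, config = occupancy_config()) {
  rows <- list()
  for (strand in c("+", "-")) {
    ref_base <- if (strand == "+") "T" else "A"
    conv_base <- if (strand == "+") "C" else "G"
    sub <- pileups[pileups$strand == strand, , drop = FALSE]
    for (key in unique(paste(sub$chrom, sub$pos))) {
      at <- sub[paste(sub$chrom, sub$pos) == key, , drop = FALSE]
      if (at$ref[1L] != ref_base) next
      total <- sum(at$count)
      conv <- sum(at$count[at$base == conv_base])
      if (conv >= config$min_converted_reads &&
          total >= config$min_total_reads &&
          conv / total >= config$min_conversion_fraction)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = at$chrom[1L], pos = at$pos[1L], strand = strand,
          converted_reads = as.numeric(conv), total_reads = as.numeric(total),
          value = as.numeric(conv), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), pos = integer(0), strand = character(0),
    converted_reads = numeric(0), total_reads = numeric(0),
    value = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
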