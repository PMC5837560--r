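# Selection of CUTs located upstream in tandem of a protein-coding gene
# with a clean gap interval between the CUT 3' end and the gene TSS.

#' Selection configuration for tandem CUT-gene pairs
#'
#' @param min_gap,max_gap Inclusive bounds (bp) on the gap interval from
#'   the CUT 3' end to the downstream gene TSS. Defaults 100 and 1500.
#' @param min_overlap_bp Shared positions needed to call two units
#'   overlapping (default 1).
#' @param stranded_overlap If `TRUE`, the CUT-vs-other-unit overlap test in
#'   [remove_overlapping_cuts()] only considers same-strand units; the
#'   default (`FALSE`) counts overlap on either strand, matching the
#'   either-strand rule used for the gap test.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(min_gap = 100L, max_gap = 1500L,
                             min_overlap_bp = 1L, stranded_overlap = FALSE) {
  min_gap <- as.integer(min_gap); max_gap <- as.integer(max_gap)
  if (is.na(min_gap) || is.na(max_gap) || min_gap <= 0L || min_gap >= max_gap)
    stop("selection config requires 0 < min_gap < max_gap")
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  structure(list(min_gap = min_gap, max_gap = max_gap,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 stranded_overlap = isTRUE(stranded_overlap)),
            class = "selection_config")
}

#' Remove CUTs overlapping any other transcription unit
#'
#' A CUT is retained only if it shares fewer than `min_overlap_bp`
#' positions with every other unit (CUTs, SUTs and genes alike), on either
#' strand by default. Half-open adjacency (one unit ending where the next
#' starts) is not overlap. A CUT never counts as overlapping itself, which
#' is decided by record id.
#'
#' @param cuts Annotation `GRanges` of CUTs.
#' @param all_units Annotation `GRanges` of every transcription unit
#'   (typically CUTs + SUTs + genes).
#' @param config A [selection_config()].
#' @return The retained subset of `cuts`.
#' @export
remove_overlapping_cuts <- function(cuts, all_units,
                                    config = selection_config()) {
  if (length(cuts) == 0L) return(cuts)
  hits <- findOverlaps(cuts, all_units,
                       minoverlap = config$min_overlap_bp,
                       ignore.strand = !config$stranded_overlap)
  not_self <- mcols(cuts)$id[queryHits(hits)] !=
    mcols(all_units)$id[subjectHits(hits)]
  cuts[!seq_along(cuts) %in% queryHits(hits)[not_self]]
}

#' Nearest same-strand downstream gene of a CUT
#'
#' "Downstream" is strand-aware: the gene TSS must lie strictly beyond the
#' CUT 3' end in the direction of transcription, on the same chromosome
#' and strand. The TSS of a plus-strand gene is its start; of a
#' minus-strand gene its (exclusive) end — mirrored for the CUT 3' end.
#' Ties at equal distance break by smaller gene start, then lexicographic
#' id.
#'
#' @param cut A single-record annotation `GRanges` (or index into `cuts`).
#' @param genes Annotation `GRanges` of genes.
#' @return `NULL` if no downstream gene exists, else a list with elements
#'   `gene` (one-record `GRanges`) and `distance` (bp from CUT 3' end to
#'   gene TSS).
#' @export
nearest_downstream_gene <- function(cut, genes) {
  stopifnot(length(cut) == 1L)
  cut_strand <- as.character(strand(cut))
  same <- genes[as.character(seqnames(genes)) == as.character(seqnames(cut)) &
                  as.character(strand(genes)) == cut_strand]
  if (length(same) == 0L) return(NULL)
  if (cut_strand == "+") {
    cut3 <- end(cut)                       # exclusive boundary coordinate
    tss <- start(same) - 1L                # 0-based gene starts
    dist <- tss - cut3
  } else {
    cut3 <- start(cut) - 1L                # 0-based boundary
    tss <- end(same)
    dist <- cut3 - tss
  }
  ok <- dist > 0L
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  ord <- order(dist[cand], start(same)[cand], mcols(same)$id[cand])
  pick <- cand[ord[1L]]
  list(gene = same[pick], distance = as.integer(dist[pick]))
}

# Gap interval between a CUT 3' end and its downstream gene TSS, on the
# shared strand, as a genomic_interval.
pair_gap <- function(cut, gene) {
  s <- as.character(strand(cut))
  if (s == "+") {
    genomic_interval(as.character(seqnames(cut)), end(cut),
                     start(gene) - 1L, "+")
  } else {
    genomic_interval(as.character(seqnames(cut)), end(gene),
                     start(cut) - 1L, "-")
  }
}

#' Select tandem CUT-gene candidate pairs
#'
#' The screen retains a CUT when (after [remove_overlapping_cuts()]) it has
#' a same-strand downstream gene whose gap interval (i) has a length within
#' `[min_gap, max_gap]`, inclusive on both ends, and (ii) contains no other
#' transcription unit on either strand — the pair's own CUT and gene are
#' exempt, though under half-open coordinates they only touch the gap.
#'
#' @param cuts Annotation `GRanges` of CUTs.
#' @param genes Annotation `GRanges` of genes.
#' @param all_units Annotation `GRanges` of every unit used for both
#'   overlap tests (CUTs + SUTs + genes).
#' @param config A [selection_config()].
#' @return A `data.frame`, one row per pair, sorted by chromosome then gap
#'   start, with columns `cut_id`, `chrom`, `cut_start`, `cut_end`,
#'   `strand`, `gene_id`, `gene_start`, `gene_end`, `gap_start`,
#'   `gap_end`, `distance` (0-based half-open coordinates).
#' @export
select_candidate_pairs <- function(cuts, genes, all_units,
                                   config = selection_config()) {
  if (!is(config, "selection_config")) stop("config must be a selection_config")
  kept <- remove_overlapping_cuts(cuts, all_units, config)
  rows <- list()
  for (i in seq_along(kept)) {
    cut <- kept[i]
    nd <- nearest_downstream_gene(cut, genes)
    if (is.null(nd)) next
    if (nd$distance < config$min_gap || nd$distance > config$max_gap) next
    gap <- pair_gap(cut, nd$gene)
    gap_gr <- iv_to_granges(gap)
    hits <- findOverlaps(gap_gr, all_units,
                         minoverlap = config$min_overlap_bp,
                         ignore.strand = TRUE)
    other <- setdiff(mcols(all_units)$id[subjectHits(hits)],
                     c(mcols(cut)$id, mcols(nd$gene)$id))
    if (length(other)) next
    rows[[length(rows) + 1L]] <- data.frame(
      cut_id = mcols(cut)$id,
      chrom = as.character(seqnames(cut)),
      cut_start = start(cut) - 1L,
      cut_end = end(cut),
      strand = as.character(strand(cut)),
      gene_id = mcols(nd$gene)$id,
      gene_start = start(nd$gene) - 1L,
      gene_end = end(nd$gene),
      gap_start = gap$start,
      gap_end = gap$end,
      distance = nd$distance,
      stringsAsFactors = FALSE)
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

# Reconstruct the gap/cut/gene genomic_intervals of one pair-table row.
pair_intervals <- function(row) {
  list(
    cut = genomic_interval(row$chrom, row$cut_start, row$cut_end, row$strand),
    gene = genomic_interval(row$chrom, row$gene_start, row$gene_end,
                            row$strand),
    gap = genomic_interval(row$chrom, row$gap_start, row$gap_end, row$strand))
}
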