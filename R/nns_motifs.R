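# NNS (Nrd1-Nab3-Sen1) RNA-binding motif counting in transcript sequences.
# Nrd1 recognizes GUAA/GUAG and Nab3 UCUU/CUUG in nascent RNA; motif
# density over a lncRNA is a rough predictor of NNS termination strength.

#' Define an NNS motif set
#'
#' @param nrd1 Character vector of Nrd1 motifs (RNA alphabet). Defaults
#'   GUAA and GUAG.
#' @param nab3 Character vector of Nab3 motifs. Defaults UCUU and CUUG.
#' @param allow_overlaps Count overlapping occurrences (default `TRUE`):
#'   binding sites are positional, not tiling.
#' @return A list of class `motif_set` with elements `motifs` (named by
#'   protein label) and `allow_overlaps`.
#' @export
motif_set <- function(nrd1 = c("GUAA", "GUAG"), nab3 = c("UCUU", "CUUG"),
                      allow_overlaps = TRUE) {
  motifs <- c(stats::setNames(rep("Nrd1", length(nrd1)), nrd1),
              stats::setNames(rep("Nab3", length(nab3)), nab3))
  seqs <- toupper(names(motifs))
  if (length(seqs) && (any(nchar(seqs) < 3L) ||
                       any(grepl("[^ACGU]", seqs))))
    stop("motifs must be RNA strings (A/C/G/U) of length >= 3")
  names(motifs) <- seqs
  structure(list(motifs = motifs, allow_overlaps = isTRUE(allow_overlaps)),
            class = "motif_set")
}

#' Extract the RNA sequence of a stranded interval
#'
#' Plus strand: the genomic substring; minus strand: its reverse
#' complement. T is rewritten to U and the result is uppercase.
#'
#' @param genome_seq A `Biostrings::DNAStringSet` (e.g. from
#'   `readDNAStringSet`) or a named character vector of chromosome
#'   sequences.
#' @param interval A [genomic_interval()].
#' @return A single RNA string.
#' @export
transcript_sequence <- function(genome_seq, interval) {
  stopifnot(is(interval, "genomic_interval"))
  if (is.character(genome_seq))
    genome_seq <- Biostrings::DNAStringSet(toupper(genome_seq))
  if (!interval$chrom %in% names(genome_seq))
    stop("chromosome not in genome sequence: ", interval$chrom)
  chr <- genome_seq[[interval$chrom]]
  if (interval$end > length(chr))
    stop("interval out of sequence bounds: ", format(interval))
  dna <- Biostrings::subseq(chr, interval$start + 1L, interval$end)
  if (interval$strand == "-") dna <- Biostrings::reverseComplement(dna)
  chartr("T", "U", toupper(as.character(dna)))
}

#' Count NNS motifs in an RNA sequence
#'
#' Occurrences are counted with a positional scan; overlapping matches
#' count separately when `allow_overlaps` is set on the motif set.
#' Counting is case-insensitive.
#'
#' @param seq RNA string over A/C/G/U.
#' @param motifs A [motif_set()].
#' @return A list with `per_motif` (named count vector) and `per_label`
#'   (totals for Nrd1 and Nab3).
#' @export
count_motifs <- function(seq, motifs = motif_set()) {
  stopifnot(is(motifs, "motif_set"))
  seq <- toupper(seq)
  bad <- gregexpr("[^ACGU]", seq)[[1L]]
  if (bad[1L] != -1L)
    stop("invalid characters in RNA sequence at position(s) ",
         paste(bad, collapse = ", "))
  if (length(motifs$motifs) == 0L)
    return(list(per_motif = stats::setNames(integer(0), character(0)),
                per_label = c(Nrd1 = 0L, Nab3 = 0L)))
  rna <- Biostrings::RNAString(seq)
  per_motif <- vapply(names(motifs$motifs), function(m) {
    hits <- Biostrings::matchPattern(Biostrings::RNAString(m), rna)
    if (motifs$allow_overlaps) length(hits)
    else length(reduce_nonoverlapping(Biostrings::start(hits), nchar(m)))
  }, 0L)
  labels <- motifs$motifs
  per_label <- c(Nrd1 = sum(per_motif[labels == "Nrd1"]),
                 Nab3 = sum(per_motif[labels == "Nab3"]))
  list(per_motif = per_motif, per_label = per_label)
}

# Greedy left-to-right selection of non-overlapping match starts.
reduce_nonoverlapping <- function(starts, width) {
  keep <- integer(0)
  last_end <- -1L
  for (s in sort(starts)) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + width - 1L
    }
  }
  keep
}

#' Append per-CUT motif counts to a pair table
#'
#' @param pairs Pair table from [select_candidate_pairs()].
#' @param genome_seq Genome sequence (see [transcript_sequence()]).
#' @param motifs A [motif_set()].
#' @return `pairs` with `nrd1_motif_count` and `nab3_motif_count` columns.
#' @export
add_motif_counts <- function(pairs, genome_seq, motifs = motif_set()) {
  counts <- lapply(seq_len(nrow(pairs)), function(i) {
    iv <- pair_intervals(pairs[i, ])$cut
    count_motifs(transcript_sequence(genome_seq, iv), motifs)$per_label
  })
  pairs$nrd1_motif_count <- vapply(counts, `[[`, 0L, "Nrd1")
  pairs$nab3_motif_count <- vapply(counts, `[[`, 0L, "Nab3")
  pairs
}
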