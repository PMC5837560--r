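# Stranded 5'-position coverage: filtering aligned reads, building tag
# tracks, library-size normalization, track subtraction and interval sums.

#' Alignment filter configuration
#'
#' @param min_mapq_exclusive Reads with MAPQ less than or equal to this are
#'   removed (default 10).
#' @param exclusion_regions Optional annotation `GRanges` of unwanted units
#'   (rRNA/tRNA/snRNA/snoRNA); reads overlapping any of them by at least
#'   one position, on either strand, are removed.
#' @return A list of class `alignment_filter_config`.
#' @export
alignment_filter_config <- function(min_mapq_exclusive = 10L,
                                    exclusion_regions = NULL) {
  min_mapq_exclusive <- as.integer(min_mapq_exclusive)
  if (is.na(min_mapq_exclusive) || min_mapq_exclusive < 0L)
    stop("min_mapq_exclusive must be a non-negative integer")
  structure(list(min_mapq_exclusive = min_mapq_exclusive,
                 exclusion_regions = exclusion_regions),
            class = "alignment_filter_config")
}

#' Read aligned reads from a SAM or BAM file
#'
#' SAM text input is converted to BAM on the fly (Rsamtools) and read back;
#' each primary alignment becomes one row. Spliced alignments contribute
#' their full reference span: downstream statistics only consume one 5'
#' tag per read.
#'
#' @param path SAM or BAM file.
#' @return A `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `mapq`, `mapped`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "cigar", "strand", "mapq", "flag"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(res$flag, 4L)
  width <- cigar_ref_width(res$cigar)
  width[is.na(width)] <- res$qwidth[is.na(width)]
  data.frame(
    chrom = as.character(res$rname),
    start = ifelse(mapped, res$pos - 1L, NA_integer_),
    end = ifelse(mapped, res$pos - 1L + width, NA_integer_),
    strand = as.character(res$strand),
    mapq = res$mapq,
    mapped = mapped,
    stringsAsFactors = FALSE)
}

# Reference span implied by a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  out
}

#' Filter aligned reads
#'
#' Drops unmapped reads, reads with MAPQ at or below the configured
#' threshold (a missing MAPQ is treated as 0 and dropped, with a message),
#' and reads overlapping any exclusion region by at least one position on
#' either strand. Input order is preserved.
#'
#' @param alignments `data.frame` as returned by [read_alignments()].
#' @param config An [alignment_filter_config()].
#' @return The surviving subset, same columns and order.
#' @export
filter_alignments <- function(alignments, config = alignment_filter_config()) {
  stopifnot(is.data.frame(alignments))
  mapq <- alignments$mapq
  if (anyNA(mapq)) {
    message(sum(is.na(mapq)), " read(s) missing MAPQ; treated as 0 and dropped")
    mapq[is.na(mapq)] <- 0L
  }
  keep <- alignments$mapped & mapq > config$min_mapq_exclusive
  excl <- config$exclusion_regions
  if (!is.null(excl) && length(excl) && any(keep)) {
    idx <- which(keep)
    gr <- GRanges(alignments$chrom[idx],
                  IRanges(alignments$start[idx] + 1L, alignments$end[idx]),
                  strand = alignments$strand[idx])
    hit <- countOverlaps(gr, excl, ignore.strand = TRUE) > 0L
    keep[idx[hit]] <- FALSE
  }
  alignments[keep, , drop = FALSE]
}

#' Build a stranded 5'-position coverage track
#'
#' Each read contributes one tag at its 5' genomic position: `start` for a
#' plus-strand read, `end - 1` for a minus-strand read. Total track mass
#' equals the read count.
#'
#' @param alignments Filtered alignment `data.frame`.
#' @param genome Named vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
five_prime_coverage <- function(alignments, genome) {
  genome <- validate_genome(genome)
  pos5 <- ifelse(alignments$strand == "+", alignments$start,
                 alignments$end - 1L)
  bad <- !alignments$chrom %in% names(genome) | pos5 < 0L |
    pos5 >= genome[alignments$chrom]
  if (any(bad))
    stop(sum(bad), " read(s) outside chromosome bounds")
  build <- function(s) {
    sel <- alignments$strand == s
    GRanges(alignments$chrom[sel], IRanges(pos5[sel] + 1L, width = 1L))
  }
  coverage_track(build("+"), build("-"), genome)
}

#' Normalize a coverage track to a fixed tag total
#'
#' Every value is scaled by `target_tags / M` where M is the total mass
#' summed over both strands (library size). The default target of one
#' million tags matches standard per-million normalization.
#'
#' @param track A non-negative `coverage_track` with positive mass.
#' @param target_tags Target total (default 1e6).
#' @return The scaled track with its `normalized` flag set.
#' @export
normalize_cpm <- function(track, target_tags = 1e6) {
  stopifnot(is(track, "coverage_track"))
  if (track$allow_negative)
    stop("cannot CPM-normalize a signed difference track")
  m <- track_mass(track)
  if (m <= 0) stop("empty track")
  f <- target_tags / m
  track$plus <- methods::as(lapply(track$plus, function(r) r * f),
                            "SimpleRleList")
  track$minus <- methods::as(lapply(track$minus, function(r) r * f),
                             "SimpleRleList")
  track$normalized <- TRUE
  track
}

#' Subtract one coverage track from another
#'
#' Per-position, per-strand difference `a - b`; the result allows negative
#' values (a signed difference track). Both tracks must share a genome; a
#' warning is raised when one is normalized and the other is not.
#'
#' @param a,b `coverage_track`s over the same genome.
#' @return A `coverage_track` with `allow_negative = TRUE`.
#' @export
subtract_tracks <- function(a, b) {
  stopifnot(is(a, "coverage_track"), is(b, "coverage_track"))
  if (!identical(a$genome[sort(names(a$genome))],
                 b$genome[sort(names(b$genome))]))
    stop("genome mismatch between tracks")
  if (xor(a$normalized, b$normalized))
    warning("subtracting a normalized track from a raw one")
  diff_strand <- function(s) {
    out <- lapply(names(a$genome), function(chr) a[[s]][[chr]] - b[[s]][[chr]])
    names(out) <- names(a$genome)
    methods::as(out, "SimpleRleList")
  }
  structure(list(plus = diff_strand("plus"), minus = diff_strand("minus"),
                 genome = a$genome, normalized = a$normalized,
                 allow_negative = TRUE),
            class = "coverage_track")
}

#' Sum track signal over an interval
#'
#' @param track A `coverage_track`.
#' @param interval A [genomic_interval()].
#' @param which_strand `"same"` sums on the interval's own strand,
#'   `"opposite"` on the other strand (the divergent direction).
#' @return Numeric scalar.
#' @export
interval_signal <- function(track, interval, which_strand = c("same",
                                                              "opposite")) {
  which_strand <- match.arg(which_strand)
  stopifnot(is(track, "coverage_track"), is(interval, "genomic_interval"))
  if (!interval$chrom %in% names(track$genome))
    stop("unknown chromosome: ", interval$chrom)
  if (interval$end > track$genome[[interval$chrom]])
    stop("interval out of bounds: ", format(interval))
  s <- interval$strand
  if (which_strand == "opposite") s <- if (s == "+") "-" else "+"
  rle <- if (s == "+") track$plus[[interval$chrom]] else
    track$minus[[interval$chrom]]
  sum(as.numeric(S4Vectors::window(rle, interval$start + 1L, interval$end)))
}
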