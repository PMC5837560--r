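# PAR-CLIP crosslink-site detection from pileup records, and
# nascent-transcription-normalized occupancy. Crosslink positions show
# diagnostic T-to-C conversions on plus-strand reads and A-to-G on
# minus-strand reads (4-thiouridine photo-crosslinking chemistry).

#' Occupancy configuration
#'
#' @param smoothing_window Odd sliding-window width (bp) for smoothing the
#'   4sU-seq nascent-transcription track (default 51, i.e. 25 bp each
#'   side of the centre).
#' @param zero_pseudocount Value substituted for zero-coverage positions
#'   inside the smoothing window before averaging (default 0.1). It is
#'   not added to nonzero positions.
#' @param min_total_reads Minimum read depth at a position to call a
#'   crosslink site (default 10).
#' @param min_converted_reads Minimum converted reads (default 2).
#' @param min_conversion_fraction Minimum converted/total fraction
#'   (default 0.01).
#' @return A list of class `occupancy_config`.
#' @export
occupancy_config <- function(smoothing_window = 51L, zero_pseudocount = 0.1,
                             min_total_reads = 10L, min_converted_reads = 2L,
                             min_conversion_fraction = 0.01) {
  smoothing_window <- as.integer(smoothing_window)
  if (is.na(smoothing_window) || smoothing_window < 1L ||
      smoothing_window %% 2L == 0L)
    stop("smoothing_window must be an odd positive integer")
  if (!is.numeric(zero_pseudocount) || zero_pseudocount <= 0)
    stop("zero_pseudocount must be positive")
  structure(list(smoothing_window = smoothing_window,
                 zero_pseudocount = zero_pseudocount,
                 min_total_reads = as.integer(min_total_reads),
                 min_converted_reads = as.integer(min_converted_reads),
                 min_conversion_fraction = min_conversion_fraction),
            class = "occupancy_config")
}

#' Read pileup records from a six-column TSV
#'
#' Long format, one row per (position, read strand, observed base):
#' columns `chrom`, `pos` (0-based), `ref`, `strand`, `base`, `count`.
#'
#' @param path TSV file (a `#`-prefixed header line is allowed).
#' @return A pileup `data.frame`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("chrom", "pos", "ref", "strand",
                                        "base", "count"),
                          colClasses = c("character", "integer",
                                         "character", "character",
                                         "character", "numeric"),
                          stringsAsFactors = FALSE)
  validate_pileup(df)
  df
}

validate_pileup <- function(pileups) {
  need <- c("chrom", "pos", "ref", "strand", "base", "count")
  if (!all(need %in% names(pileups)))
    stop("pileup records need columns ", paste(need, collapse = ", "))
  if (any(pileups$count < 0)) stop("pileup counts must be non-negative")
  if (!all(pileups$ref %in% c("A", "C", "G", "T")))
    stop("pileup ref bases must be A/C/G/T")
  invisible(pileups)
}

#' Detect PAR-CLIP crosslink sites
#'
#' A plus-strand site is emitted at a position whose reference base is T
#' when, among plus-strand reads, the C count is at least
#' `min_converted_reads`, the total depth is at least `min_total_reads`,
#' and the conversion fraction is at least `min_conversion_fraction`.
#' Mirrored on the minus strand (reference A, G conversions on
#' minus-strand reads). The site value is the converted read count.
#'
#' @param pileups Pileup `data.frame` (see [read_pileup()]), sorted by
#'   chromosome then position.
#' @param config An [occupancy_config()].
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`,
#'   `converted_reads`, `total_reads`, `value`.
#' @export
detect_crosslink_sites <- function(pileups, config = occupancy_config()) {
  validate_pileup(pileups)
  key <- paste(pileups$chrom, formatC(pileups$pos, width = 12, flag = "0"))
  if (is.unsorted(key)) stop("pileup records must be sorted by chrom, pos")
  call_strand <- function(read_strand, ref_base, conv_base, out_strand) {
    sel <- pileups$strand == read_strand
    if (!any(sel)) return(NULL)
    sub <- pileups[sel, , drop = FALSE]
    grp <- paste(sub$chrom, sub$pos)
    total <- tapply(sub$count, grp, sum)
    conv <- tapply(ifelse(sub$base == conv_base, sub$count, 0), grp, sum)
    ref <- tapply(sub$ref, grp, `[[`, 1L)
    first <- !duplicated(grp)
    ord <- match(unique(grp), names(total))
    df <- data.frame(chrom = sub$chrom[first], pos = sub$pos[first],
                     ref = as.character(ref[ord]),
                     total = as.numeric(total[ord]),
                     conv = as.numeric(conv[ord]),
                     stringsAsFactors = FALSE)
    ok <- df$ref == ref_base &
      df$conv >= config$min_converted_reads &
      df$total >= config$min_total_reads &
      df$conv / df$total >= config$min_conversion_fraction
    if (!any(ok)) return(NULL)
    df <- df[ok, , drop = FALSE]
    data.frame(chrom = df$chrom, pos = df$pos, strand = out_strand,
               converted_reads = df$conv, total_reads = df$total,
               value = df$conv, stringsAsFactors = FALSE)
  }
  out <- rbind(call_strand("+", "T", "C", "+"),
               call_strand("-", "A", "G", "-"))
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), converted_reads = numeric(0),
                      total_reads = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert crosslink sites to a normalized coverage track
#'
#' Per-position value is the converted read count, then the track is
#' normalized to one million tags (see [normalize_cpm()]).
#'
#' @param sites Site table from [detect_crosslink_sites()].
#' @param genome Named vector of chromosome lengths.
#' @param target_tags Normalization target (default 1e6).
#' @return A normalized `coverage_track`.
#' @export
crosslink_track <- function(sites, genome, target_tags = 1e6) {
  if (anyDuplicated(sites[c("chrom", "pos", "strand")]))
    stop("duplicate crosslink sites (chrom, pos, strand)")
  genome <- validate_genome(genome)
  build <- function(s) {
    sel <- sites$strand == s
    GRanges(sites$chrom[sel], IRanges(sites$pos[sel] + 1L, width = 1L),
            score = sites$value[sel])
  }
  normalize_cpm(coverage_track(build("+"), build("-"), genome),
                target_tags = target_tags)
}

# Truncated centred sliding mean over a numeric vector; zero positions are
# replaced by `pc` before averaging, windows shrink at the ends. Windows
# lying entirely within one constant run are assigned that value directly,
# so constant regions (and all-zero chromosomes) are exact fixed points
# rather than accumulating cumsum round-off.
windowed_mean <- function(x, window, pc) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  y <- ifelse(x > 0, x, pc)
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in which(runs$lengths >= window)) {
    a <- if (starts[i] == 1L) 1L else starts[i] + h
    b <- if (ends[i] == n) n else ends[i] - h
    if (a <= b) out[a:b] <- runs$values[i]
  }
  out
}

#' Smooth a nascent-transcription (4sU-seq) track
#'
#' Per strand and chromosome, each position's value becomes the mean over
#' the centred `smoothing_window`, with zero-coverage positions replaced
#' by `zero_pseudocount` inside the window and windows truncated at
#' chromosome ends (no padding). The result is strictly positive
#' everywhere, so it can serve as a divisor.
#'
#' @param nascent Non-negative `coverage_track`.
#' @param config An [occupancy_config()].
#' @return A `coverage_track` of smoothed values.
#' @export
smooth_nascent <- function(nascent, config = occupancy_config()) {
  stopifnot(is(nascent, "coverage_track"))
  if (nascent$allow_negative) stop("nascent track must be non-negative")
  smooth_strand <- function(strand) {
    out <- lapply(names(nascent$genome), function(chr) {
      S4Vectors::Rle(windowed_mean(as.numeric(nascent[[strand]][[chr]]),
                                   config$smoothing_window,
                                   config$zero_pseudocount))
    })
    names(out) <- names(nascent$genome)
    methods::as(out, "SimpleRleList")
  }
  coverage_track(smooth_strand("plus"), smooth_strand("minus"),
                 nascent$genome, normalized = nascent$normalized)
}

#' Nascent-normalized PAR-CLIP occupancy
#'
#' Divides the PAR-CLIP crosslink signal by the smoothed nascent
#' transcription signal, per position and strand. Positions with zero
#' PAR-CLIP signal are zero (absent) in the output.
#'
#' @param parclip Crosslink `coverage_track` (e.g. [crosslink_track()]).
#' @param smoothed_nascent Output of [smooth_nascent()]; must be strictly
#'   positive wherever `parclip` is nonzero.
#' @return A `coverage_track` of occupancy values.
#' @export
normalized_occupancy <- function(parclip, smoothed_nascent) {
  stopifnot(is(parclip, "coverage_track"),
            is(smoothed_nascent, "coverage_track"))
  if (!identical(parclip$genome[sort(names(parclip$genome))],
                 smoothed_nascent$genome[sort(names(smoothed_nascent$genome))]))
    stop("genome mismatch between PAR-CLIP and nascent tracks")
  div_strand <- function(strand) {
    out <- lapply(names(parclip$genome), function(chr) {
      p <- as.numeric(parclip[[strand]][[chr]])
      s <- as.numeric(smoothed_nascent[[strand]][[chr]])
      bad <- p != 0 & s <= 0
      if (any(bad))
        stop("zero/negative nascent value under PAR-CLIP signal on ", chr,
             " (", strand, "); was the nascent track smoothed?")
      S4Vectors::Rle(ifelse(p != 0, p / s, 0))
    })
    names(out) <- names(parclip$genome)
    methods::as(out, "SimpleRleList")
  }
  coverage_track(div_strand("plus"), div_strand("minus"), parclip$genome,
                 normalized = parclip$normalized)
}

#' Occupancy of an interval
#'
#' Sum of normalized occupancy values over the interval on its own strand
#' (the sum, rather than the mean, preserves site-count information; pass
#' `aggregate = "mean"` for a per-position mean).
#'
#' @param occ Occupancy `coverage_track`.
#' @param interval A [genomic_interval()].
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return Numeric scalar.
#' @export
occupancy_over_interval <- function(occ, interval,
                                    aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  total <- interval_signal(occ, interval, "same")
  if (aggregate == "mean") total / iv_width(interval) else total
}
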