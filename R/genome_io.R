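#' @importFrom GenomicRanges GRanges seqnames start end strand coverage
#'   findOverlaps countOverlaps mcols mcols<- reduce
#' @importFrom IRanges IRanges ranges width
#' @importFrom S4Vectors Rle runValue runLength queryHits subjectHits
#' @importFrom methods as is
NULL

# ---- genomic intervals -----------------------------------------------------

#' Create a stranded genomic interval
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' `start` is the first base covered, `end` is one past the last. Wig input
#' (1-based) is converted on read so a single convention holds internally.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start (bp).
#' @param end Exclusive end (bp); must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ",", end, ")")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d) %s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:[%d,%d)%s", x$chrom, x$start, x$end, x$strand)
}

iv_width <- function(iv) iv$end - iv$start

# 5' end (TSS) and 3' end of a stranded interval, as 0-based half-open
# boundary coordinates: on "+" the TSS is `start` and the 3' end is `end`;
# mirrored on "-" where transcription runs leftward.
iv_tss <- function(iv) if (iv$strand == "+") iv$start else iv$end
iv_3p <- function(iv) if (iv$strand == "+") iv$end else iv$start

iv_to_granges <- function(iv) {
  GRanges(iv$chrom, IRanges(iv$start + 1L, iv$end), strand = iv$strand)
}

# ---- annotation sets -------------------------------------------------------

ANNOT_CLASSES <- c("CUT", "SUT", "gene", "other")

#' Build an annotation set of classed transcription units
#'
#' An annotation set is a `GRanges` carrying `id` and `class` metadata
#' columns (class one of CUT/SUT/gene/other) with optional chromosome
#' lengths in its seqinfo. Input coordinates are 0-based half-open and are
#' converted to the 1-based closed convention `GRanges` uses; accessors in
#' this package convert back, so user-facing coordinates stay BED-like.
#'
#' @param id Character vector of unique record ids.
#' @param class Annotation class, recycled; one of `"CUT"`, `"SUT"`,
#'   `"gene"`, `"other"`.
#' @param chrom,start,end,strand Parallel vectors of 0-based half-open
#'   stranded coordinates.
#' @param genome Optional named vector of chromosome lengths (bp). When
#'   given, every interval is validated against it.
#' @return A `GRanges` with mcols `id`, `class`.
#' @export
annotation_set <- function(id, class, chrom, start, end, strand,
                           genome = NULL) {
  n <- length(id)
  if (n == 0L) {
    gr <- GRanges()
    mcols(gr)$id <- character(0)
    mcols(gr)$class <- character(0)
    return(set_annot_genome(gr, genome))
  }
  class <- rep_len(as.character(class), n)
  if (anyDuplicated(id))
    stop("annotation ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!all(class %in% ANNOT_CLASSES))
    stop("annotation class must be one of ", paste(ANNOT_CLASSES, collapse = "/"))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L | start >= end))
    stop("invalid interval coordinates (need 0 <= start < end)")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every record")
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  mcols(gr)$id <- as.character(id)
  mcols(gr)$class <- class
  set_annot_genome(gr, genome)
}

set_annot_genome <- function(gr, genome) {
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    missing_chr <- setdiff(as.character(unique(seqnames(gr))), names(genome))
    if (length(missing_chr))
      stop("chromosome(s) absent from genome: ",
           paste(missing_chr, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    # bounds are validated below with a specific message; the stock
    # out-of-bound warning from seqlengths<- would duplicate it
    suppressWarnings(GenomeInfoDb::seqlengths(gr) <- unname(genome))
    bad <- end(gr) > genome[as.character(seqnames(gr))]
    if (any(bad))
      stop("interval(s) exceed chromosome length: ",
           paste(mcols(gr)$id[bad], collapse = ", "))
  }
  gr
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome lengths")
  storage.mode(genome) <- "integer"
  if (any(is.na(genome)) || any(genome <= 0L))
    stop("chromosome lengths must be positive integers")
  genome
}

annot_genome <- function(annot) {
  sl <- GenomeInfoDb::seqlengths(annot)
  if (all(is.na(sl))) NULL else sl
}

# 0-based start of an annotation record i (BED convention)
annot_start0 <- function(annot) start(annot) - 1L

#' Read a chromosome-length table
#'
#' Accepts a two-column chrom/length TSV or a FASTA index (`.fai`), of
#' which only the first two columns are used.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("genome file needs at least two columns")
  validate_genome(stats::setNames(as.integer(tab[[2L]]),
                                  as.character(tab[[1L]])))
}

#' Read BED6 annotations
#'
#' @param path BED file with at least 6 columns (strand required).
#' @param class_label Class applied to every record (CUT/SUT/gene/other).
#' @param genome Optional chromosome lengths for bounds validation; when
#'   absent, bounds validation is skipped (a message notes this).
#' @return Annotation `GRanges` (see [annotation_set()]).
#' @export
read_annotations <- function(path, class_label = "other", genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L)
    return(annotation_set(character(0), character(0), character(0),
                          integer(0), integer(0), character(0), genome))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BED line ", lineno[which(nf < 6L)[1L]],
         " in ", path, ": fewer than 6 columns (strand required)")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1L]], " in ", path,
         ": non-numeric coordinates")
  if (is.null(genome))
    message("no genome lengths supplied; bounds validation disabled for ", path)
  annotation_set(name, class_label, chrom, start, end, strand, genome)
}

# ---- stranded coverage tracks ----------------------------------------------

#' Construct a stranded coverage track
#'
#' A coverage track stores one numeric value per genomic position and
#' strand, held as a per-chromosome run-length encoded list for each
#' strand. Minus-strand values are stored non-negated: the strand is
#' carried structurally, never as a sign.
#'
#' @param plus,minus Per-strand signal, either an `RleList` (one run-length
#'   vector per chromosome) or a `GRanges` with a `score` column (0-based
#'   inputs are not expected here; `GRanges` are 1-based as usual).
#' @param genome Named vector of chromosome lengths.
#' @param normalized Logical flag recording whether [normalize_cpm()] has
#'   been applied.
#' @param allow_negative Allow negative values (difference tracks).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(plus, minus, genome, normalized = FALSE,
                           allow_negative = FALSE) {
  genome <- validate_genome(genome)
  plus <- as_strand_rle(plus, genome)
  minus <- as_strand_rle(minus, genome)
  track <- structure(list(plus = plus, minus = minus, genome = genome,
                          normalized = normalized,
                          allow_negative = allow_negative),
                     class = "coverage_track")
  validate_track(track)
  track
}

as_strand_rle <- function(x, genome) {
  if (is(x, "GRanges")) {
    GenomeInfoDb::seqlevels(x) <- names(genome)
    GenomeInfoDb::seqlengths(x) <- unname(genome)
    x <- coverage(x, weight = if ("score" %in% names(mcols(x))) "score" else 1L)
  }
  if (is.list(x) && !is(x, "RleList"))
    x <- methods::as(lapply(x, S4Vectors::Rle), "SimpleRleList")
  if (!is(x, "RleList")) stop("strand signal must be an RleList or GRanges")
  out <- lapply(names(genome), function(chr) {
    if (chr %in% names(x)) {
      r <- x[[chr]]
      if (length(r) != genome[[chr]])
        stop("coverage length for ", chr, " (", length(r),
             ") does not match chromosome length (", genome[[chr]], ")")
      S4Vectors::Rle(as.numeric(runValue(r)), runLength(r))
    } else {
      S4Vectors::Rle(0, genome[[chr]])
    }
  })
  names(out) <- names(genome)
  methods::as(out, "SimpleRleList")
}

validate_track <- function(track) {
  for (s in c("plus", "minus")) {
    vals <- unlist(lapply(track[[s]], runValue), use.names = FALSE)
    if (length(vals) && any(!is.finite(vals)))
      stop("non-finite coverage values on ", s, " strand")
    if (!track$allow_negative && length(vals) && any(vals < 0))
      stop("negative coverage values on ", s,
           " strand (use allow_negative for difference tracks)")
  }
  invisible(track)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "stranded coverage track: %d chromosome(s), mass %.6g%s%s\n",
    length(x$genome), track_mass(x),
    if (x$normalized) ", normalized" else "",
    if (x$allow_negative) ", signed" else ""))
  invisible(x)
}

#' Total signal mass of a track (both strands)
#' @param track A `coverage_track`.
#' @return Numeric scalar.
#' @export
track_mass <- function(track) {
  sum(vapply(track$plus, sum, 0)) + sum(vapply(track$minus, sum, 0))
}

# Value at a single 0-based position; mainly for tests and spot checks.
#' @export
track_value <- function(track, chrom, pos, strand) {
  stopifnot(strand %in% c("+", "-"))
  rle <- if (strand == "+") track$plus[[chrom]] else track$minus[[chrom]]
  if (is.null(rle)) stop("unknown chromosome: ", chrom)
  if (pos < 0L || pos >= length(rle)) stop("position out of bounds")
  as.numeric(rle[pos + 1L])
}

# ---- coverage I/O ----------------------------------------------------------

guess_coverage_format <- function(path) {
  if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE)) "wig" else "bedGraph"
}

read_one_strand <- function(path, format, allow_negative) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0L) return(gr)
  if (is.null(mcols(gr)$score)) stop("no score column in ", path)
  if (any(countOverlaps(gr, gr) > 1L))
    stop("overlapping intervals in ", path)
  if (!allow_negative && any(mcols(gr)$score < 0))
    stop("negative values in ", path,
         " (pass allow_negative = TRUE for difference tracks)")
  gr
}

#' Read a stranded coverage track from per-strand bedGraph or Wig files
#'
#' Each bedGraph interval `[s, e)` with value v expands to per-position
#' value v for positions s..e-1 on that file's strand; positions not
#' covered by any interval carry 0. Wig files (fixedStep or variableStep,
#' 1-based) are converted to the internal 0-based convention on read.
#'
#' @param path_plus,path_minus Per-strand coverage files.
#' @param genome Optional chromosome lengths; inferred from the data when
#'   absent (bounds validation then only reflects observed extents).
#' @param format `"auto"` (by extension), `"bedGraph"` or `"wig"`.
#' @param allow_negative Accept negative values (difference tracks).
#' @param normalized Mark the returned track as already normalized.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path_plus, path_minus, genome = NULL,
                          format = c("auto", "bedGraph", "wig"),
                          allow_negative = FALSE, normalized = FALSE) {
  format <- match.arg(format)
  fmt_p <- if (format == "auto") guess_coverage_format(path_plus) else format
  fmt_m <- if (format == "auto") guess_coverage_format(path_minus) else format
  gp <- read_one_strand(path_plus, fmt_p, allow_negative)
  gm <- read_one_strand(path_minus, fmt_m, allow_negative)
  if (is.null(genome)) {
    chroms <- union(as.character(seqnames(gp)), as.character(seqnames(gm)))
    if (length(chroms) == 0L)
      stop("cannot infer genome from two empty coverage files")
    genome <- vapply(chroms, function(chr) {
      max(0L, end(gp)[as.character(seqnames(gp)) == chr],
          end(gm)[as.character(seqnames(gm)) == chr])
    }, 0L)
    message("genome lengths inferred from coverage extents")
  }
  genome <- validate_genome(genome)
  check_bounds <- function(gr, path) {
    bad <- !as.character(seqnames(gr)) %in% names(genome) |
      end(gr) > genome[as.character(seqnames(gr))]
    if (any(bad)) stop("interval outside genome bounds in ", path)
  }
  check_bounds(gp, path_plus); check_bounds(gm, path_minus)
  coverage_track(gp, gm, genome, normalized = normalized,
                 allow_negative = allow_negative)
}

#' Write a stranded coverage track as two bedGraph files
#'
#' Adjacent equal-valued positions are merged into maximal intervals,
#' zero-valued positions are omitted, and lines are ordered by chromosome
#' (lexicographic) then start. Values are written with full double
#' precision so a read/write round trip is exact.
#'
#' @param track A `coverage_track`.
#' @param path_prefix Output prefix; files are written as
#'   `<prefix>_plus.bedgraph` and `<prefix>_minus.bedgraph`.
#' @param header Optional comment lines (without `#`) recorded at the top
#'   of each file, e.g. the simulation seed.
#' @return Invisibly, the two file paths.
#' @export
write_coverage <- function(track, path_prefix, header = NULL) {
  stopifnot(is(track, "coverage_track"))
  paths <- c(plus = paste0(path_prefix, "_plus.bedgraph"),
             minus = paste0(path_prefix, "_minus.bedgraph"))
  write_strand <- function(s) {
    con <- file(paths[[s]], open = "wt")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    for (chr in sort(names(track$genome))) {
      r <- track[[s]][[chr]]
      ends <- cumsum(runLength(r))
      starts <- ends - runLength(r)      # 0-based starts
      vals <- runValue(r)
      keep <- vals != 0
      if (!any(keep)) next
      writeLines(sprintf("%s\t%d\t%d\t%.17g", chr, starts[keep],
                         ends[keep], vals[keep]), con)
    }
  }
  write_strand("plus")
  write_strand("minus")
  invisible(paths)
}
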