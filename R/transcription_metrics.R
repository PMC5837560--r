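# Per-pair summary statistics: promoter directionality from NET-seq 5'
# tags, and the Nrd1-depletion read-through index from Pol II PAR-CLIP.

#' Directionality configuration
#'
#' @param window Window size in bp for both the coding and divergent
#'   signal (default 100).
#' @param pseudocount Added to the divergent signal before division to
#'   avoid dividing by zero (default 0.25).
#' @return A list of class `directionality_config`.
#' @export
directionality_config <- function(window = 100L, pseudocount = 0.25) {
  window <- as.integer(window)
  if (is.na(window) || window <= 0L) stop("window must be a positive integer")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  structure(list(window = window, pseudocount = pseudocount),
            class = "directionality_config")
}

# First `w` bp of a stranded interval in the direction of transcription.
first_window <- function(iv, w) {
  w <- min(w, iv_width(iv))
  if (iv$strand == "+")
    genomic_interval(iv$chrom, iv$start, iv$start + w, "+")
  else
    genomic_interval(iv$chrom, iv$end - w, iv$end, "-")
}

# Last `w` bp of a stranded interval in the direction of transcription.
last_window <- function(iv, w) {
  w <- min(w, iv_width(iv))
  if (iv$strand == "+")
    genomic_interval(iv$chrom, iv$end - w, iv$end, "+")
  else
    genomic_interval(iv$chrom, iv$start, iv$start + w, "-")
}

#' Promoter directionality of a downstream gene
#'
#' The coding intensity is the NET-seq 5'-tag signal over the first
#' `window` bp of the gene on the coding strand; the divergent intensity
#' is the signal over the last `window` bp of the gap interval on the
#' opposite strand. The index is `coding / (divergent + pseudocount)`.
#' Gaps or genes shorter than the window truncate it (a message notes
#' this).
#'
#' @param netseq NET-seq `coverage_track` (5'-position tags).
#' @param pair One row of the pair table from [select_candidate_pairs()].
#' @param config A [directionality_config()].
#' @return A list with `coding_signal`, `divergent_signal`, `index`.
#' @export
directionality_index <- function(netseq, pair,
                                 config = directionality_config()) {
  iv <- pair_intervals(pair)
  if (iv_width(iv$gap) < config$window)
    message("gap shorter than window for ", pair$cut_id,
            "; divergent window truncated to ", iv_width(iv$gap), " bp")
  if (iv_width(iv$gene) < config$window)
    message("gene shorter than window for ", pair$gene_id,
            "; coding window truncated to ", iv_width(iv$gene), " bp")
  coding <- interval_signal(netseq, first_window(iv$gene, config$window),
                            "same")
  divergent <- interval_signal(netseq, last_window(iv$gap, config$window),
                               "opposite")
  list(coding_signal = coding, divergent_signal = divergent,
       index = coding / (divergent + config$pseudocount))
}

#' Nrd1-depletion read-through index
#'
#' The ratio of Pol II PAR-CLIP signal at the gap interval over the signal
#' at the CUT body in the depletion (treatment) sample, relative to the
#' same ratio in the control sample:
#' `((gap_t + ps) / (cut_t + ps)) / ((gap_c + ps) / (cut_c + ps))`.
#' All four signals are measured on the CUT strand. The pseudocount
#' defaults to 0: a zero denominator is a hard error naming the pair
#' rather than silently added mass.
#'
#' @param treatment,control Pol II PAR-CLIP `coverage_track`s normalized
#'   to the same tag target (a warning is raised otherwise).
#' @param pair One row of the pair table.
#' @param pseudocount Added to each of the four signals (default 0).
#' @param gap_strand `"same"` (default) restricts the gap signal to the
#'   CUT strand; `"both"` sums both strands over the gap.
#' @return A list with `gap_treatment`, `cut_treatment`, `gap_control`,
#'   `cut_control` and `index`.
#' @export
readthrough_index <- function(treatment, control, pair, pseudocount = 0,
                              gap_strand = c("same", "both")) {
  gap_strand <- match.arg(gap_strand)
  if (!treatment$normalized || !control$normalized)
    warning("read-through index computed on unnormalized track(s)")
  iv <- pair_intervals(pair)
  gap_sig <- function(track) {
    s <- interval_signal(track, iv$gap, "same")
    if (gap_strand == "both") s <- s + interval_signal(track, iv$gap,
                                                       "opposite")
    s
  }
  gap_t <- gap_sig(treatment) + pseudocount
  cut_t <- interval_signal(treatment, iv$cut, "same") + pseudocount
  gap_c <- gap_sig(control) + pseudocount
  cut_c <- interval_signal(control, iv$cut, "same") + pseudocount
  if (cut_t == 0 || cut_c == 0 || gap_c == 0)
    stop("read-through index undefined for pair ", pair$cut_id,
         ": zero denominator (consider a pseudocount)")
  list(gap_treatment = gap_t - pseudocount,
       cut_treatment = cut_t - pseudocount,
       gap_control = gap_c - pseudocount,
       cut_control = cut_c - pseudocount,
       index = (gap_t / cut_t) / (gap_c / cut_c))
}

#' Append directionality and read-through columns to a pair table
#'
#' @param pairs Pair table from [select_candidate_pairs()].
#' @param netseq NET-seq `coverage_track`, or `NULL` to skip.
#' @param treatment,control Pol II PAR-CLIP `coverage_track`s, or `NULL`
#'   to skip the read-through columns.
#' @param dir_config,readthrough_pseudocount Passed through to
#'   [directionality_index()] and [readthrough_index()].
#' @return `pairs` with columns `directionality_coding`,
#'   `directionality_divergent`, `directionality_index` and/or
#'   `readthrough_index` appended.
#' @export
add_transcription_metrics <- function(pairs, netseq = NULL,
                                      treatment = NULL, control = NULL,
                                      dir_config = directionality_config(),
                                      readthrough_pseudocount = 0) {
  if (!is.null(netseq)) {
    res <- lapply(seq_len(nrow(pairs)), function(i)
      directionality_index(netseq, pairs[i, ], dir_config))
    pairs$directionality_coding <- vapply(res, `[[`, 0, "coding_signal")
    pairs$directionality_divergent <- vapply(res, `[[`, 0, "divergent_signal")
    pairs$directionality_index <- vapply(res, `[[`, 0, "index")
  }
  if (!is.null(treatment) && !is.null(control)) {
    pairs$readthrough_index <- vapply(seq_len(nrow(pairs)), function(i)
      readthrough_index(treatment, control, pairs[i, ],
                        pseudocount = readthrough_pseudocount)$index, 0)
  }
  pairs
}
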