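# Quantification of the bench assays: ChIP-qPCR enrichment and gated
# flow-cytometry fluorescence, plus replicate-level summary statistics.

#' Percent input recovered by immunoprecipitation (%IP)
#'
#' %IP = 2^(CT_input - CT_ip) * (dilution_input / dilution_ip). The
#' default dilutions (input 1/100, IP 1/50) contribute a factor of exactly
#' 2. The statistic is scale-free in CT: adding the same number of cycles
#' to both CT values leaves it unchanged.
#'
#' @param ct_input,ct_ip Threshold-cycle values (finite numerics,
#'   vectorized).
#' @param dilution_input,dilution_ip Fold dilutions (> 0); defaults 100
#'   and 50.
#' @return Numeric vector of fractions.
#' @export
percent_ip <- function(ct_input, ct_ip, dilution_input = 100,
                       dilution_ip = 50) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip)))
    stop("CT values must be finite")
  if (any(dilution_input <= 0) || any(dilution_ip <= 0))
    stop("dilution factors must be positive")
  2^(ct_input - ct_ip) * (dilution_input / dilution_ip)
}

#' Relative enrichment
#'
#' Ratio of a target %IP to a reference %IP; used both for normalization
#' to a household gene (e.g. ACT1) and for chromatin-mark-to-histone
#' ratios (e.g. H3K36me3 relative to total H3).
#'
#' @param target,reference Numeric values; `reference` must be positive.
#' @return `target / reference`.
#' @export
relative_enrichment <- function(target, reference) {
  if (any(reference <= 0)) stop("reference enrichment must be positive")
  target / reference
}

#' Gate flow-cytometry events
#'
#' Events are sorted by acquisition time, the first floor(n/3) and last
#' floor(n/9) are dropped (unstable sample flow at run edges), then only
#' events with side scatter within +-`ssc_band` of the survivors' median
#' SSC are kept (removes debris and aggregates, compares cells of similar
#' size). A well whose gated count falls below `min_events` is excluded
#' as a verdict, not an error.
#'
#' @param events `data.frame` with columns `time`, `ssc` and one or more
#'   fluorescence channels (e.g. `yfp`, `mcherry`).
#' @param min_events Minimum gated events to keep the well (default 500).
#' @param ssc_band Half-width of the SSC band as a fraction of the median
#'   (default 0.25).
#' @param head_fraction,tail_fraction Fractions of events dropped from the
#'   start and end of the run (defaults 1/3 and 1/9).
#' @return A list of class `gated_well`: `events` (gated subset),
#'   `excluded` (logical), `n_input`, `n_after_time`, `n_gated`.
#' @export
gate_events <- function(events, min_events = 500L, ssc_band = 0.25,
                        head_fraction = 1 / 3, tail_fraction = 1 / 9) {
  stopifnot(is.data.frame(events), all(c("time", "ssc") %in% names(events)))
  if (nrow(events) == 0L) stop("no events supplied")
  if (head_fraction <= 0 || head_fraction >= 1 ||
      tail_fraction <= 0 || tail_fraction >= 1)
    stop("trim fractions must lie in (0, 1)")
  ev <- events[order(events$time), , drop = FALSE]
  n <- nrow(ev)
  drop_head <- floor(n * head_fraction)
  drop_tail <- floor(n * tail_fraction)
  if (drop_head + drop_tail >= n) {
    ev <- ev[0L, , drop = FALSE]
  } else {
    ev <- ev[seq.int(drop_head + 1L, n - drop_tail), , drop = FALSE]
  }
  n_after_time <- nrow(ev)
  if (n_after_time > 0L) {
    med <- stats::median(ev$ssc)
    ev <- ev[ev$ssc >= (1 - ssc_band) * med &
               ev$ssc <= (1 + ssc_band) * med, , drop = FALSE]
  }
  structure(list(events = ev, excluded = nrow(ev) < min_events,
                 n_input = n, n_after_time = n_after_time,
                 n_gated = nrow(ev)),
            class = "gated_well")
}

#' Background-subtracted, reference-normalized fluorescence
#'
#' Per strain, the mean of the chosen channel over gated events minus the
#' mean of the background strain (no fluorescent reporter), divided by
#' the background-subtracted mean of the co-assayed wild-type reference
#' strain. The reference strain itself therefore scores exactly 1.
#'
#' @param gated_wells Named list of `gated_well` objects (names are strain
#'   labels).
#' @param background_strain,reference_strain Strain labels present in
#'   `gated_wells` and not excluded.
#' @param channel Fluorescence channel column, `"yfp"` or `"mcherry"`.
#' @return Named numeric vector of normalized means (excluded wells are
#'   `NA`).
#' @export
fluorescence_summary <- function(gated_wells, background_strain,
                                 reference_strain,
                                 channel = c("yfp", "mcherry")) {
  channel <- match.arg(channel)
  stopifnot(is.list(gated_wells), !is.null(names(gated_wells)))
  for (lbl in c(background_strain, reference_strain)) {
    if (!lbl %in% names(gated_wells)) stop("strain not assayed: ", lbl)
    if (gated_wells[[lbl]]$excluded)
      stop("strain excluded by gating: ", lbl)
  }
  well_mean <- function(w) {
    if (!channel %in% names(w$events))
      stop("channel missing from events: ", channel)
    mean(w$events[[channel]])
  }
  bg <- well_mean(gated_wells[[background_strain]])
  ref_net <- well_mean(gated_wells[[reference_strain]]) - bg
  if (ref_net <= 0)
    stop("reference strain has non-positive background-subtracted signal")
  vapply(gated_wells, function(w) {
    if (w$excluded) return(NA_real_)
    (well_mean(w) - bg) / ref_net
  }, 0)
}

#' Replicate summary with unpaired two-sided t-test
#'
#' Mean and standard error of the mean per group; when both groups have
#' at least two replicates, a two-tailed unpaired Student's t-test
#' (pooled variance by default; set `var_equal = FALSE` for Welch) with
#' significance stars at p < 0.05 (*), < 0.01 (**) and < 0.001 (***).
#'
#' @param values Numeric vector of per-replicate means (group 1).
#' @param comparison Optional numeric vector for group 2.
#' @param var_equal Pooled-variance Student's test (default `TRUE`).
#' @return A list with `mean`, `sem`, and when a comparison is given and
#'   testable, `comparison_mean`, `comparison_sem`, `t`, `df`, `p_value`,
#'   `stars`.
#' @export
replicate_summary <- function(values, comparison = NULL, var_equal = TRUE) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(mean = mean(values), sem = sem(values), n = length(values))
  if (!is.null(comparison)) {
    out$comparison_mean <- mean(comparison)
    out$comparison_sem <- sem(comparison)
    out$comparison_n <- length(comparison)
    if (length(values) >= 2L && length(comparison) >= 2L) {
      tt <- stats::t.test(values, comparison, var.equal = var_equal,
                          alternative = "two.sided")
      out$t <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_value <- tt$p.value
      out$stars <- significance_stars(tt$p.value)
    } else {
      message("fewer than 2 replicates in a group; summary only, no test")
    }
  }
  out
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Read qPCR CT tables / flow event tables from CSV
#'
#' Thin readers for the tidy CSV layouts the simulators emit: qPCR rows
#' carry `locus`, `antibody`, `replicate`, `ct_input`, `ct_ip`,
#' `dilution_input`, `dilution_ip`; flow rows carry `well`, `strain`,
#' `time`, `ssc`, `yfp`, `mcherry`.
#'
#' @param path CSV file (a `#`-prefixed comment header is allowed).
#' @return A `data.frame`.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("qPCR file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_qpcr
#' @export
read_flow_events <- function(path) {
  if (!file.exists(path)) stop("flow event file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
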