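# Synthetic annotation, coverage, pileup, qPCR and flow fixtures with
# known ground truth, so every pipeline stage can be exercised end to end
# without external data. The tag model is Poisson per position (no read
# length structure): all downstream statistics consume 5'-tag counts only.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; generators are deterministic given (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_sim_genome <- function() c(chrS1 = 200000L, chrS2 = 200000L)

#' Simulate a tandem CUT-gene annotation with decoys
#'
#' Places `n_valid` cassettes that satisfy the selection criteria (tandem
#' same-strand CUT then gene, gap length within the configured range,
#' clean gap) plus three controlled decoy classes: CUTs overlapped by
#' another unit, pairs whose gap contains an interloping SUT, and pairs
#' whose gap length falls outside the allowed range. The truth table
#' records which CUTs a correct screen must recover, together with the
#' per-locus transcription parameters used by the coverage simulators:
#' termination efficiency theta (read-through fraction 1 - theta),
#' depletion effect delta (theta_depleted = theta * (1 - delta)), CUT and
#' gene tag rates (expected tags/bp) and the promoter's divergent
#' fraction.
#'
#' @param n_valid Number of cassettes satisfying all criteria.
#' @param n_overlap_decoys,n_interloper_decoys,n_gap_decoys Decoy counts
#'   (defaults 2 each).
#' @param genome Named chromosome lengths; default two 200-kb chromosomes
#'   (keeps a full-pipeline run fast while leaving room for decoys).
#' @param config [selection_config()] whose gap range the valid cassettes
#'   respect.
#' @param theta,delta,lambda_cut,lambda_gene,divergent_fraction Per-CUT
#'   parameter vectors, recycled over all cassettes. Defaults: theta
#'   drawn from U(0.6, 0.95), delta 0.5, lambda_cut 1 tag/bp, lambda_gene
#'   5 tags/bp, divergent_fraction 0.2.
#' @param seed RNG seed; recorded in the truth and in every file header
#'   written from this simulation.
#' @return A list of class `cut_sim` with `annotation` (all units),
#'   `cuts`, `genes` (annotation subsets), `truth` (data.frame), `genome`,
#'   `seed`.
#' @export
simulate_annotation <- function(n_valid = 10L, n_overlap_decoys = 2L,
                                n_interloper_decoys = 2L, n_gap_decoys = 2L,
                                genome = default_sim_genome(),
                                config = selection_config(),
                                theta = NULL, delta = 0.5, lambda_cut = 1,
                                lambda_gene = 5, divergent_fraction = 0.2,
                                seed = 1L) {
  genome <- validate_genome(genome)
  n_total <- n_valid + n_overlap_decoys + n_interloper_decoys + n_gap_decoys
  with_seed(seed, {
    if (is.null(theta)) theta <- stats::runif(max(n_total, 1L), 0.6, 0.95)
    theta <- rep_len(theta, max(n_total, 1L))
    delta <- rep_len(delta, max(n_total, 1L))
    lambda_cut <- rep_len(lambda_cut, max(n_total, 1L))
    lambda_gene <- rep_len(lambda_gene, max(n_total, 1L))
    divergent_fraction <- rep_len(divergent_fraction, max(n_total, 1L))
    types <- c(rep("valid", n_valid), rep("overlap", n_overlap_decoys),
               rep("interloper", n_interloper_decoys),
               rep("gap", n_gap_decoys))
    if (n_total > 0L) types <- sample(types)   # interleave along the genome

    pad <- 400L
    cursor <- stats::setNames(rep(500L, length(genome)), names(genome))
    recs <- list()
    truth <- list()
    add_rec <- function(id, class, chrom, start, end, strand)
      recs[[length(recs) + 1L]] <<- data.frame(
        id = id, class = class, chrom = chrom, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE)

    for (i in seq_len(n_total)) {
      type <- types[i]
      cut_len <- sample(200:600, 1L)
      gene_len <- sample(1000:2000, 1L)
      gap_len <- if (type == "gap") {
        if (stats::runif(1) < 0.5) sample(10:(config$min_gap - 1L), 1L)
        else sample((config$max_gap + 1L):(config$max_gap + 1000L), 1L)
      } else if (type == "interloper") {
        sample(500:config$max_gap, 1L)     # room for the interloper
      } else {
        sample(config$min_gap:config$max_gap, 1L)
      }
      strand <- sample(c("+", "-"), 1L)
      span <- cut_len + gap_len + gene_len
      chrom <- NA_character_
      for (chr in names(genome)) {
        if (cursor[[chr]] + span + pad <= genome[[chr]] - 500L) {
          chrom <- chr; break
        }
      }
      if (is.na(chrom))
        stop("infeasible packing: genome too small for requested cassettes")
      at <- cursor[[chrom]]
      cursor[[chrom]] <- at + span + pad

      # left-to-right order depends on strand: transcription runs CUT ->
      # gap -> gene in its own direction
      if (strand == "+") {
        cut_start <- at; cut_end <- at + cut_len
        gene_start <- cut_end + gap_len; gene_end <- gene_start + gene_len
      } else {
        gene_start <- at; gene_end <- at + gene_len
        cut_start <- gene_end + gap_len; cut_end <- cut_start + cut_len
      }
      cid <- sprintf("simCUT%03d", i)
      gid <- sprintf("simGENE%03d", i)
      add_rec(cid, "CUT", chrom, cut_start, cut_end, strand)
      add_rec(gid, "gene", chrom, gene_start, gene_end, strand)
      if (type == "overlap") {
        # a SUT overlapping the CUT body on the opposite strand
        os <- cut_start + cut_len %/% 3L
        add_rec(sprintf("simSUTov%03d", i), "SUT", chrom, os,
                os + max(100L, cut_len %/% 2L),
                if (strand == "+") "-" else "+")
      }
      if (type == "interloper") {
        # a SUT strictly inside the gap interval
        gs <- if (strand == "+") cut_end else gene_end
        add_rec(sprintf("simSUTin%03d", i), "SUT", chrom, gs + 100L,
                gs + 100L + max(100L, gap_len %/% 3L),
                sample(c("+", "-"), 1L))
      }
      truth[[i]] <- data.frame(
        cut_id = cid, gene_id = gid, chrom = chrom, strand = strand,
        cut_start = cut_start, cut_end = cut_end,
        gene_start = gene_start, gene_end = gene_end,
        gap_length = gap_len, type = type, valid = type == "valid",
        theta = theta[i], delta = delta[i], lambda_cut = lambda_cut[i],
        lambda_gene = lambda_gene[i],
        divergent_fraction = divergent_fraction[i],
        stringsAsFactors = FALSE)
    }
    recs <- if (length(recs)) do.call(rbind, recs) else
      data.frame(id = character(0), class = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(cut_id = character(0), valid = logical(0))
    annotation <- annotation_set(recs$id, recs$class, recs$chrom, recs$start,
                                 recs$end, recs$strand, genome)
    structure(list(annotation = annotation,
                   cuts = annotation[mcols(annotation)$class == "CUT"],
                   genes = annotation[mcols(annotation)$class == "gene"],
                   truth = truth, genome = genome, seed = seed),
              class = "cut_sim")
  })
}

# Poisson-sample a dense stranded track from per-position rate vectors.
sample_track_from_rates <- function(rates, genome) {
  lists <- lapply(c("plus", "minus"), function(s) {
    out <- lapply(names(genome), function(chr) {
      lambda <- rates[[s]][[chr]]
      if (is.null(lambda) || all(lambda == 0))
        S4Vectors::Rle(0, genome[[chr]])
      else
        S4Vectors::Rle(as.numeric(stats::rpois(genome[[chr]], lambda)))
    })
    names(out) <- names(genome)
    methods::as(out, "SimpleRleList")
  })
  coverage_track(lists[[1L]], lists[[2L]], genome)
}

empty_rates <- function(genome) {
  one <- lapply(genome, function(L) numeric(L))
  list(plus = one, minus = one)
}

# Add `rate` over 0-based [start, end) on `strand` of a rates structure.
add_rate <- function(rates, chrom, start, end, strand, rate) {
  s <- if (strand == "+") "plus" else "minus"
  idx <- (start + 1L):end
  rates[[s]][[chrom]][idx] <- rates[[s]][[chrom]][idx] + rate
  rates
}

#' Simulate a NET-seq 5'-tag track
#'
#' Per-position Poisson tags: gene bodies carry `lambda_gene` on the
#' coding strand; each promoter emits divergent transcription at
#' `lambda_gene * divergent_fraction` on the opposite strand over the
#' 200 bp upstream of the gene TSS (within the gap); CUT bodies carry
#' `lambda_cut` on their own strand.
#'
#' @param sim A `cut_sim` from [simulate_annotation()].
#' @param seed RNG seed.
#' @param divergent_span Width (bp) of the divergent-emission zone
#'   upstream of each TSS (default 200).
#' @return A raw (unnormalized) `coverage_track`.
#' @export
simulate_netseq <- function(sim, seed = sim$seed + 1L,
                            divergent_span = 200L) {
  stopifnot(is(sim, "cut_sim"))
  with_seed(seed, {
    rates <- empty_rates(sim$genome)
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      rates <- add_rate(rates, tr$chrom, tr$gene_start, tr$gene_end,
                        tr$strand, tr$lambda_gene)
      rates <- add_rate(rates, tr$chrom, tr$cut_start, tr$cut_end,
                        tr$strand, tr$lambda_cut)
      if (tr$divergent_fraction > 0) {
        span <- min(divergent_span, tr$gap_length)
        opp <- if (tr$strand == "+") "-" else "+"
        if (tr$strand == "+")
          rates <- add_rate(rates, tr$chrom, tr$gene_start - span,
                            tr$gene_start, opp,
                            tr$lambda_gene * tr$divergent_fraction)
        else
          rates <- add_rate(rates, tr$chrom, tr$gene_end,
                            tr$gene_end + span, opp,
                            tr$lambda_gene * tr$divergent_fraction)
      }
    }
    sample_track_from_rates(rates, sim$genome)
  })
}

#' Simulate a Pol II PAR-CLIP depletion/control track pair with pileups
#'
#' Control sample: CUT bodies at rate `lambda_cut`, gap intervals at
#' `lambda_cut * (1 - theta)` (the read-through fraction that escapes
#' termination). Treatment (Nrd1-depleted) sample: identical CUT bodies,
#' gaps at `lambda_cut * (1 - theta * (1 - delta))`. All signal is on the
#' CUT strand. Pileup records plant T-to-C (plus strand) / A-to-G (minus
#' strand) conversions at `sites_per_cut` positions per CUT at the given
#' depth and conversion probability, plus non-T/non-A reference positions
#' that a correct caller must never report.
#'
#' @param sim A `cut_sim`.
#' @param seed RNG seed.
#' @param depth Read depth at each planted crosslink site (default 50).
#' @param conversion_probability Per-read conversion probability
#'   (default 0.5).
#' @param sites_per_cut Planted crosslink sites per CUT (default 3).
#' @param n_noise_positions Non-T/non-A reference pileup positions added
#'   as false-positive bait (default 20).
#' @return A list with `treatment` and `control` (`coverage_track`s),
#'   `pileups` (long-format data.frame), and `sites` (planted-site truth
#'   with `chrom`, `pos`, `strand`).
#' @export
simulate_parclip_pair <- function(sim, seed = sim$seed + 2L, depth = 50L,
                                  conversion_probability = 0.5,
                                  sites_per_cut = 3L,
                                  n_noise_positions = 20L) {
  stopifnot(is(sim, "cut_sim"))
  with_seed(seed, {
    ctrl <- empty_rates(sim$genome)
    trt <- empty_rates(sim$genome)
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      gap <- if (tr$strand == "+")
        c(tr$cut_end, tr$gene_start) else c(tr$gene_end, tr$cut_start)
      ctrl <- add_rate(ctrl, tr$chrom, tr$cut_start, tr$cut_end, tr$strand,
                       tr$lambda_cut)
      trt <- add_rate(trt, tr$chrom, tr$cut_start, tr$cut_end, tr$strand,
                      tr$lambda_cut)
      if (gap[2L] > gap[1L]) {
        ctrl <- add_rate(ctrl, tr$chrom, gap[1L], gap[2L], tr$strand,
                         tr$lambda_cut * (1 - tr$theta))
        trt <- add_rate(trt, tr$chrom, gap[1L], gap[2L], tr$strand,
                        tr$lambda_cut * (1 - tr$theta * (1 - tr$delta)))
      }
    }
    control <- sample_track_from_rates(ctrl, sim$genome)
    treatment <- sample_track_from_rates(trt, sim$genome)

    pile <- list()
    sites <- list()
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      k <- min(sites_per_cut, tr$cut_end - tr$cut_start)
      pos <- sort(sample(tr$cut_start:(tr$cut_end - 1L), k))
      ref <- if (tr$strand == "+") "T" else "A"
      conv_base <- if (tr$strand == "+") "C" else "G"
      conv <- stats::rbinom(k, depth, conversion_probability)
      pile[[length(pile) + 1L]] <- data.frame(
        chrom = tr$chrom, pos = rep(pos, 2L), ref = ref,
        strand = tr$strand,
        base = c(rep(conv_base, k), rep(ref, k)),
        count = c(conv, depth - conv), stringsAsFactors = FALSE)
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = tr$chrom, pos = pos, strand = tr$strand,
        converted = conv, depth = depth, stringsAsFactors = FALSE)
    }
    if (n_noise_positions > 0L && length(sim$genome)) {
      chrom <- sample(names(sim$genome), n_noise_positions, replace = TRUE)
      pos <- vapply(chrom, function(ch)
        sample.int(sim$genome[[ch]], 1L) - 1L, 0L)
      pile[[length(pile) + 1L]] <- data.frame(
        chrom = chrom, pos = pos,
        ref = sample(c("G", "C"), n_noise_positions, replace = TRUE),
        strand = sample(c("+", "-"), n_noise_positions, replace = TRUE),
        base = sample(c("A", "C", "G", "T"), n_noise_positions,
                      replace = TRUE),
        count = sample(10:60, n_noise_positions, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    pileups <- do.call(rbind, pile)
    pileups <- pileups[order(pileups$chrom, pileups$pos), , drop = FALSE]
    rownames(pileups) <- NULL
    list(treatment = treatment, control = control, pileups = pileups,
         sites = do.call(rbind, sites))
  })
}

#' Simulate a 4sU-seq nascent-transcription track
#'
#' Gene bodies and CUT bodies carry their truth rates on the coding
#' strand; everywhere else is zero. Used as the denominator track for
#' occupancy normalization after smoothing.
#'
#' @param sim A `cut_sim`.
#' @param seed RNG seed.
#' @return A raw `coverage_track`.
#' @export
simulate_nascent <- function(sim, seed = sim$seed + 3L) {
  stopifnot(is(sim, "cut_sim"))
  with_seed(seed, {
    rates <- empty_rates(sim$genome)
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      rates <- add_rate(rates, tr$chrom, tr$gene_start, tr$gene_end,
                        tr$strand, tr$lambda_gene)
      rates <- add_rate(rates, tr$chrom, tr$cut_start, tr$cut_end,
                        tr$strand, tr$lambda_cut)
    }
    sample_track_from_rates(rates, sim$genome)
  })
}

#' Simulate a qPCR CT table from known enrichments
#'
#' For each enrichment e, `ct_ip = ct_input - log2(e * dilution_ip /
#' dilution_input) + N(0, noise_sd)`, so [percent_ip()] recovers e in
#' expectation (up to the small log-normal bias of the noise).
#'
#' @param enrichments Named numeric vector of true %IP values (> 0).
#' @param n_replicates Replicates per locus (default 3).
#' @param noise_sd Gaussian CT noise in cycles (default 0.1).
#' @param ct_input Input CT value (default 20).
#' @param dilution_input,dilution_ip Fold dilutions (defaults 100, 50).
#' @param seed RNG seed.
#' @return A `data.frame` with columns `locus`, `replicate`, `ct_input`,
#'   `ct_ip`, `dilution_input`, `dilution_ip`, `true_enrichment`.
#' @export
simulate_qpcr <- function(enrichments, n_replicates = 3L, noise_sd = 0.1,
                          ct_input = 20, dilution_input = 100,
                          dilution_ip = 50, seed = 1L) {
  if (any(enrichments <= 0)) stop("enrichment values must be positive")
  if (is.null(names(enrichments)))
    names(enrichments) <- sprintf("locus%02d", seq_along(enrichments))
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        locus = names(enrichments),
                        stringsAsFactors = FALSE)
    e <- enrichments[rows$locus]
    data.frame(
      locus = rows$locus, replicate = rows$replicate,
      ct_input = ct_input,
      ct_ip = ct_input - log2(e * dilution_ip / dilution_input) +
        stats::rnorm(nrow(rows), 0, noise_sd),
      dilution_input = dilution_input, dilution_ip = dilution_ip,
      true_enrichment = unname(e), stringsAsFactors = FALSE)
  })
}

#' Simulate flow-cytometry wells
#'
#' Per strain: log-normal side scatter, Gaussian fluorescence around
#' `background + net mean`, a planted debris fraction at extreme SSC, and
#' a planted early-time drift population with shifted fluorescence — the
#' artifacts the gating rules are designed to remove.
#'
#' @param strains `data.frame` with columns `strain`, `yfp`, `mcherry`
#'   (net channel means above background).
#' @param n_events Events per well (default 2000).
#' @param background Named vector of autofluorescence offsets (defaults
#'   yfp 10, mcherry 10).
#' @param channel_cv Coefficient of variation of each channel
#'   (default 0.15); the sd floor is 2 units.
#' @param debris_fraction Fraction of events with extreme SSC
#'   (default 0.02).
#' @param drift_fraction Fraction of the earliest events whose
#'   fluorescence is shifted by 50 percent (default 0.1).
#' @param ssc_meanlog,ssc_sdlog Log-normal SSC parameters (defaults
#'   log(1000) and 0.08, so the +-25 percent median band retains nearly
#'   all intact cells).
#' @param seed RNG seed.
#' @return A `data.frame` of events: `well`, `strain`, `time`, `ssc`,
#'   `yfp`, `mcherry`.
#' @export
simulate_flow <- function(strains, n_events = 2000L,
                          background = c(yfp = 10, mcherry = 10),
                          channel_cv = 0.15, debris_fraction = 0.02,
                          drift_fraction = 0.1, ssc_meanlog = log(1000),
                          ssc_sdlog = 0.08, seed = 1L) {
  stopifnot(is.data.frame(strains),
            all(c("strain", "yfp", "mcherry") %in% names(strains)))
  with_seed(seed, {
    wells <- lapply(seq_len(nrow(strains)), function(i) {
      st <- strains[i, ]
      time <- sort(stats::runif(n_events, 0, 60))
      ssc <- stats::rlnorm(n_events, ssc_meanlog, ssc_sdlog)
      n_debris <- round(n_events * debris_fraction)
      if (n_debris > 0L) {
        idx <- sample.int(n_events, n_debris)
        ssc[idx] <- ssc[idx] * sample(c(8, 0.1), n_debris, replace = TRUE)
      }
      ch <- function(net, bg) {
        mu <- bg + net
        x <- stats::rnorm(n_events, mu, pmax(channel_cv * mu, 2))
        drift_n <- round(n_events * drift_fraction)
        if (drift_n > 0L)
          x[seq_len(drift_n)] <- x[seq_len(drift_n)] * 1.5
        x
      }
      data.frame(well = sprintf("W%02d", i), strain = st$strain,
                 time = time, ssc = ssc,
                 yfp = ch(st$yfp, background[["yfp"]]),
                 mcherry = ch(st$mcherry, background[["mcherry"]]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, wells)
  })
}

#' Write a complete demo dataset from one simulation
#'
#' Materializes the exact plain-text formats the pipeline consumes:
#' BED6 annotations (one file per class), stranded bedGraph pairs for
#' NET-seq, PAR-CLIP treatment/control and 4sU-seq, the pileup TSV, a
#' qPCR CSV and a flow-event CSV. Every file header records the seed.
#'
#' @param sim A `cut_sim`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to the individual simulators.
#' @return Invisibly, a named list of the written paths.
#' @export
write_simulation_fixtures <- function(sim, dir, ...) {
  stopifnot(is(sim, "cut_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("seed: ", sim$seed)
  paths <- list()

  write_bed <- function(annot, path) {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    if (length(annot))
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                         as.character(seqnames(annot)), start(annot) - 1L,
                         end(annot), mcols(annot)$id,
                         as.character(strand(annot))), con)
    path
  }
  for (cls in unique(mcols(sim$annotation)$class)) {
    sub <- sim$annotation[mcols(sim$annotation)$class == cls]
    paths[[paste0("bed_", cls)]] <-
      write_bed(sub, file.path(dir, paste0(tolower(cls), "s.bed")))
  }
  paths$genome <- file.path(dir, "genome.tsv")
  utils::write.table(data.frame(names(sim$genome), unname(sim$genome)),
                     paths$genome, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  netseq <- simulate_netseq(sim)
  paths$netseq <- write_coverage(netseq, file.path(dir, "netseq"),
                                 header = hdr)
  pc <- simulate_parclip_pair(sim)
  paths$parclip_treatment <- write_coverage(
    pc$treatment, file.path(dir, "polii_parclip_nrd1_depleted"), header = hdr)
  paths$parclip_control <- write_coverage(
    pc$control, file.path(dir, "polii_parclip_control"), header = hdr)
  nascent <- simulate_nascent(sim)
  paths$nascent <- write_coverage(nascent, file.path(dir, "nascent_4su"),
                                  header = hdr)
  paths$pileup <- file.path(dir, "parclip_pileup.tsv")
  con <- file(paths$pileup, "wt")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(pc$pileups, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)

  qpcr <- simulate_qpcr(c(ATP16_promoter = 0.06, ATP16_body = 0.03,
                          ACT1 = 0.05), seed = sim$seed + 4L, ...)
  paths$qpcr <- file.path(dir, "chip_qpcr_ct.csv")
  writeLines(paste0("# ", hdr), paths$qpcr)
  suppressWarnings(utils::write.table(
    qpcr, paths$qpcr, sep = ",", quote = FALSE, row.names = FALSE,
    append = TRUE))
  flow <- simulate_flow(data.frame(strain = c("background", "reference",
                                              "circuitII"),
                                   yfp = c(0, 40, 16),
                                   mcherry = c(0, 30, 28)),
                        seed = sim$seed + 5L)
  paths$flow <- file.path(dir, "flow_events.csv")
  writeLines(paste0("# ", hdr), paths$flow)
  suppressWarnings(utils::write.table(
    flow, paths$flow, sep = ",", quote = FALSE, row.names = FALSE,
    append = TRUE))
  invisible(paths)
}

#' Simulate a random genome sequence for a simulation's chromosomes
#'
#' Uniform random A/C/G/T of the right lengths; used when motif counting
#' is exercised on synthetic annotations (the counts then reflect the
#' background motif frequency of random sequence).
#'
#' @param sim A `cut_sim`.
#' @param seed RNG seed.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @export
simulate_genome_sequence <- function(sim, seed = sim$seed + 6L) {
  stopifnot(is(sim, "cut_sim"))
  with_seed(seed, {
    seqs <- vapply(names(sim$genome), function(chr) {
      paste(sample(c("A", "C", "G", "T"), sim$genome[[chr]],
                   replace = TRUE), collapse = "")
    }, "")
    Biostrings::DNAStringSet(seqs)
  })
}
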