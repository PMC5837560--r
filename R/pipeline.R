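# End-to-end screen: select tandem CUT-gene pairs and append the
# directionality, read-through, occupancy and motif columns into one
# candidate table.

#' Pipeline configuration
#'
#' Bundles file paths and stage configurations for [run_screen()]. All
#' stage defaults are the screen's canonical constants: gap 100-1500 bp,
#' 100 bp directionality windows with pseudocount 0.25, 51 bp occupancy
#' smoothing with pseudocount 0.1, one-million-tag normalization.
#'
#' @param genome Path to a chrom/length TSV (see [read_genome()]).
#' @param cuts_bed,suts_bed,genes_bed BED6 annotation paths (`suts_bed`
#'   optional).
#' @param netseq_prefix Optional prefix of a stranded NET-seq bedGraph
#'   pair (`<prefix>_plus.bedgraph` / `<prefix>_minus.bedgraph`).
#' @param parclip_treatment_prefix,parclip_control_prefix Optional
#'   prefixes of the Pol II PAR-CLIP depletion and control track pairs.
#' @param nrd1_pileup,nab3_pileup Optional PAR-CLIP pileup TSVs.
#' @param nascent_prefix Optional 4sU-seq track prefix (required with a
#'   pileup).
#' @param genome_fasta Optional genome FASTA for motif counting.
#' @param output_dir Where [run_screen()] writes the candidate table and
#'   manifest.
#' @param selection,directionality,occupancy,motifs Stage configurations.
#' @param seed Seed recorded in the manifest (the screen itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, cuts_bed, genes_bed, suts_bed = NULL,
                            netseq_prefix = NULL,
                            parclip_treatment_prefix = NULL,
                            parclip_control_prefix = NULL,
                            nrd1_pileup = NULL, nab3_pileup = NULL,
                            nascent_prefix = NULL, genome_fasta = NULL,
                            output_dir = ".",
                            selection = selection_config(),
                            directionality = directionality_config(),
                            occupancy = occupancy_config(),
                            motifs = motif_set(), seed = 1L) {
  structure(list(genome = genome, cuts_bed = cuts_bed,
                 genes_bed = genes_bed, suts_bed = suts_bed,
                 netseq_prefix = netseq_prefix,
                 parclip_treatment_prefix = parclip_treatment_prefix,
                 parclip_control_prefix = parclip_control_prefix,
                 nrd1_pileup = nrd1_pileup, nab3_pileup = nab3_pileup,
                 nascent_prefix = nascent_prefix,
                 genome_fasta = genome_fasta, output_dir = output_dir,
                 selection = selection, directionality = directionality,
                 occupancy = occupancy, motifs = motifs, seed = seed),
            class = "pipeline_config")
}

prefix_paths <- function(prefix) {
  c(paste0(prefix, "_plus.bedgraph"), paste0(prefix, "_minus.bedgraph"))
}

read_prefix <- function(prefix, genome, stage) {
  paths <- prefix_paths(prefix)
  for (p in paths)
    if (!file.exists(p))
      stop(stage, ": missing coverage file ", p)
  read_coverage(paths[1L], paths[2L], genome)
}

# Occupancy column for one pileup file: call crosslink sites, CPM-scale
# them, divide by smoothed nascent signal, and sum over each CUT body.
occupancy_column <- function(pileup_path, smoothed, genome, pairs, config) {
  sites <- detect_crosslink_sites(read_pileup(pileup_path), config)
  occ <- normalized_occupancy(crosslink_track(sites, genome), smoothed)
  vapply(seq_len(nrow(pairs)), function(i)
    occupancy_over_interval(occ, pair_intervals(pairs[i, ])$cut), 0)
}

#' Run the tandem CUT-gene screen end to end
#'
#' Loads annotations, selects candidate pairs, and appends whichever
#' metric columns the configured inputs support: NET-seq promoter
#' directionality, Pol II PAR-CLIP read-through index, 4sU-normalized
#' Nrd1/Nab3 occupancy over each CUT, and NNS motif counts. Writes
#' `candidate_pairs.tsv` and `manifest.txt` (configuration constants,
#' input checksums, seed, per-stage record counts) under `output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The candidate table, invisibly.
#' @export
run_screen <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  for (f in c(config$genome, config$cuts_bed, config$genes_bed))
    if (!file.exists(f)) stop("input file not found: ", f)
  genome <- read_genome(config$genome)
  cuts <- read_annotations(config$cuts_bed, "CUT", genome)
  genes <- read_annotations(config$genes_bed, "gene", genome)
  all_units <- c(cuts, genes)
  if (!is.null(config$suts_bed)) {
    suts <- read_annotations(config$suts_bed, "SUT", genome)
    all_units <- c(all_units, suts)
  }
  counts <- c(cuts_loaded = length(cuts))
  kept <- remove_overlapping_cuts(cuts, all_units, config$selection)
  counts["cuts_after_overlap_removal"] <- length(kept)
  pairs <- select_candidate_pairs(cuts, genes, all_units, config$selection)
  counts["final_pairs"] <- nrow(pairs)
  message("screen: ", counts[["cuts_loaded"]], " CUTs loaded, ",
          counts[["cuts_after_overlap_removal"]],
          " after overlap removal, ", counts[["final_pairs"]],
          " final pairs")

  netseq <- treatment <- control <- NULL
  if (!is.null(config$netseq_prefix))
    netseq <- normalize_cpm(read_prefix(config$netseq_prefix, genome,
                                        "directionality"))
  if (!is.null(config$parclip_treatment_prefix) ||
      !is.null(config$parclip_control_prefix)) {
    if (is.null(config$parclip_treatment_prefix) ||
        is.null(config$parclip_control_prefix))
      stop("readthrough: both treatment and control tracks are required")
    treatment <- normalize_cpm(read_prefix(config$parclip_treatment_prefix,
                                           genome, "readthrough"))
    control <- normalize_cpm(read_prefix(config$parclip_control_prefix,
                                         genome, "readthrough"))
  }
  pairs <- add_transcription_metrics(pairs, netseq, treatment, control,
                                     dir_config = config$directionality)

  if (!is.null(config$nrd1_pileup) || !is.null(config$nab3_pileup)) {
    if (is.null(config$nascent_prefix))
      stop("occupancy: a nascent (4sU-seq) track prefix is required")
    nascent <- read_prefix(config$nascent_prefix, genome, "occupancy")
    smoothed <- smooth_nascent(nascent, config$occupancy)
    if (!is.null(config$nrd1_pileup))
      pairs$nrd1_occupancy <- occupancy_column(config$nrd1_pileup, smoothed,
                                               genome, pairs,
                                               config$occupancy)
    if (!is.null(config$nab3_pileup))
      pairs$nab3_occupancy <- occupancy_column(config$nab3_pileup, smoothed,
                                               genome, pairs,
                                               config$occupancy)
  }
  if (!is.null(config$genome_fasta)) {
    seqs <- Biostrings::readDNAStringSet(config$genome_fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    pairs <- add_motif_counts(pairs, seqs, config$motifs)
  }

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  table_path <- file.path(config$output_dir, "candidate_pairs.tsv")
  utils::write.table(pairs, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, counts, file.path(config$output_dir,
                                           "manifest.txt"))
  invisible(pairs)
}

write_manifest <- function(config, counts, path) {
  inputs <- Filter(function(x) is.character(x) && length(x) == 1L &&
                     file.exists(x),
                   config[c("genome", "cuts_bed", "suts_bed", "genes_bed",
                            "nrd1_pileup", "nab3_pileup", "genome_fasta")])
  prefixes <- Filter(Negate(is.null),
                     config[c("netseq_prefix", "parclip_treatment_prefix",
                              "parclip_control_prefix", "nascent_prefix")])
  for (p in prefixes) inputs <- c(inputs, as.list(prefix_paths(p)))
  sums <- tools::md5sum(unlist(inputs))
  lines <- c(
    "tandem CUT-gene screen manifest",
    paste0("seed: ", config$seed),
    paste0("min_gap: ", config$selection$min_gap),
    paste0("max_gap: ", config$selection$max_gap),
    paste0("directionality_window: ", config$directionality$window),
    paste0("directionality_pseudocount: ",
           config$directionality$pseudocount),
    paste0("smoothing_window: ", config$occupancy$smoothing_window),
    paste0("zero_pseudocount: ", config$occupancy$zero_pseudocount),
    paste0("normalization_target_tags: 1e+06"),
    paste0(names(counts), ": ", counts),
    "input checksums (md5):",
    paste0("  ", names(sums), ": ", sums))
  writeLines(lines, path)
  invisible(path)
}
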