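test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  s1 <- simulate_annotation(n_valid = 5, seed = 99)
  s2 <- simulate_annotation(n_valid = 5, seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(annot_df(s1$annotation), annot_df(s2$annotation))
  t1 <- simulate_netseq(s1, seed = 7)
  t2 <- simulate_netseq(s2, seed = 7)
  expect_identical(lapply(t1$plus, as.numeric), lapply(t2$plus, as.numeric))

  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(simulate_annotation(n_valid = 3, seed = 1))
  expect_identical(stats::runif(3), before)
})

test_that("the screen recovers exactly the planted valid pairs", {
  for (seed in c(3, 8, 15)) {
    sim <- simulate_annotation(n_valid = 8, n_overlap_decoys = 3,
                               n_interloper_decoys = 3, n_gap_decoys = 3,
                               seed = seed)
    pairs <- select_candidate_pairs(sim$cuts, sim$genes, sim$annotation)
    expect_setequal(pairs$cut_id, sim$truth$cut_id[sim$truth$valid])
    # and the selection equals the brute-force oracle on the same input
    expect_identical(pairs, oracle_select_pairs(sim$annotation))
  }
  expect_equal(nrow(simulate_annotation(n_valid = 0, n_overlap_decoys = 0,
                                        n_interloper_decoys = 0,
                                        n_gap_decoys = 0, seed = 1)$truth),
               0L)
})

test_that("NET-seq simulation reproduces the planted intensities", {
  sim <- simulate_annotation(n_valid = 6, n_overlap_decoys = 0,
                             n_interloper_decoys = 0, n_gap_decoys = 0,
                             divergent_fraction = 0, lambda_gene = 5,
                             seed = 4)
  net <- simulate_netseq(sim)
  pairs <- select_candidate_pairs(sim$cuts, sim$genes, sim$annotation)
  for (i in seq_len(nrow(pairs))) {
    d <- directionality_index(net, pairs[i, ])
    # no divergent transcription planted
    expect_equal(d$divergent_signal, 0)
    # coding signal ~ Poisson(100 * 5): within 3 sigma of the mean
    expect_lt(abs(d$coding_signal - 500), 3 * sqrt(500))
    expect_equal(d$index, d$coding_signal / 0.25)
  }
  # lambda = 0 everywhere gives an empty track
  sim0 <- simulate_annotation(n_valid = 2, n_overlap_decoys = 0,
                              n_interloper_decoys = 0, n_gap_decoys = 0,
                              lambda_cut = 0, lambda_gene = 0,
                              divergent_fraction = 0, seed = 5)
  expect_equal(track_mass(simulate_netseq(sim0)), 0)
})

test_that("PAR-CLIP pair simulation encodes theta and delta in the gap", {
  sim <- simulate_annotation(n_valid = 6, n_overlap_decoys = 0,
                             n_interloper_decoys = 0, n_gap_decoys = 0,
                             theta = 0.8, delta = 0.9, lambda_cut = 2,
                             seed = 21)
  pc <- simulate_parclip_pair(sim)
  pairs <- select_candidate_pairs(sim$cuts, sim$genes, sim$annotation)
  # expected index (1 - theta(1-delta)) / (1 - theta) = 0.92 / 0.2 = 4.6;
  # averaged over pairs the realized index should be in that vicinity
  idx <- vapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(readthrough_index(pc$treatment, pc$control,
                                       pairs[i, ]))$index, 0)
  expect_gt(mean(idx), 2)
  expect_lt(mean(idx), 8)
})

test_that("planted crosslink sites are detected at default settings", {
  sim <- simulate_annotation(n_valid = 5, seed = 33)
  pc <- simulate_parclip_pair(sim, depth = 30, conversion_probability = 0.5)
  sites <- detect_crosslink_sites(pc$pileups)
  planted <- paste(pc$sites$chrom, pc$sites$pos, pc$sites$strand)
  found <- paste(sites$chrom, sites$pos, sites$strand)
  expect_true(all(planted %in% found))
})

test_that("simulated qPCR inverts the %IP formula", {
  # no noise: ct_ip differs from ct_input by exactly -log2(e * dip/din)
  tab <- simulate_qpcr(c(x = 0.0625), n_replicates = 2, noise_sd = 0,
                       seed = 2)
  expect_equal(unique(tab$ct_input - tab$ct_ip), -5)
  expect_equal(percent_ip(tab$ct_input, tab$ct_ip), rep(0.0625, 2))

  tab1 <- simulate_qpcr(c(x = 1), n_replicates = 1, noise_sd = 0,
                        dilution_input = 100, dilution_ip = 100, seed = 2)
  expect_equal(tab1$ct_ip, tab1$ct_input)

  # with noise, recovery is unbiased to within 5% over 100 replicates
  tab2 <- simulate_qpcr(c(x = 0.2), n_replicates = 100, noise_sd = 0.1,
                        seed = 6)
  rec <- mean(percent_ip(tab2$ct_input, tab2$ct_ip))
  expect_lt(abs(rec - 0.2) / 0.2, 0.05)
})

test_that("simulated flow wells carry the planted artifacts", {
  strains <- data.frame(strain = c("bg", "ref", "s1"),
                        yfp = c(0, 40, 20), mcherry = c(0, 30, 30))
  ev <- simulate_flow(strains, n_events = 1800, seed = 12)
  expect_setequal(unique(ev$strain), strains$strain)
  # a 100-event well cannot reach 500 gated events
  tiny <- simulate_flow(strains[1, ], n_events = 100, seed = 12)
  expect_true(gate_events(tiny)$excluded)
})

test_that("gating removes planted debris and keeps in-band events", {
  strains <- data.frame(strain = "s", yfp = 30, mcherry = 30)
  ev <- simulate_flow(strains, n_events = 4000, debris_fraction = 0.05,
                      seed = 41)
  g <- gate_events(ev)
  med <- stats::median(g$events$ssc)
  # debris was planted at 8x / 0.1x typical SSC: none can sit inside a
  # +-25% band around an in-band median
  expect_equal(sum(g$events$ssc > 2 * med | g$events$ssc < med / 2), 0L)
})

test_that("fixture files round trip through the package readers", {
  sim <- simulate_annotation(n_valid = 4, seed = 77)
  dir <- tempfile()
  paths <- write_simulation_fixtures(sim, dir)
  genome <- read_genome(paths$genome)
  expect_equal(genome, sim$genome)
  cuts <- read_annotations(file.path(dir, "cuts.bed"), "CUT", genome)
  expect_equal(length(cuts), length(sim$cuts))
  expect_identical(annot_df(cuts), annot_df(sim$cuts))
  # seed recorded in headers
  expect_match(readLines(file.path(dir, "cuts.bed"), n = 1L), "seed: 77")
  expect_match(readLines(paths$netseq[["plus"]], n = 1L), "seed: 77")
  net <- read_coverage(paths$netseq[["plus"]], paths$netseq[["minus"]],
                       genome)
  ref <- simulate_netseq(sim)
  expect_identical(lapply(net$plus, as.numeric),
                   lapply(ref$plus, as.numeric))
  pile <- read_pileup(paths$pileup)
  expect_gt(nrow(pile), 0)
  expect_true(all(c("chrom", "pos", "ref", "strand", "base", "count")
                  %in% names(pile)))
})

test_that("infeasible packing errors instead of silently clashing", {
  expect_error(simulate_annotation(n_valid = 100,
                                   genome = c(tiny = 20000L), seed = 1),
               "infeasible")
})
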