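genomeP <- c(chrA = 2000L, chrB = 1500L)

pile <- function(chrom, pos, ref, strand, base, count)
  data.frame(chrom = chrom, pos = pos, ref = ref, strand = strand,
             base = base, count = count, stringsAsFactors = FALSE)

test_that("crosslink calling applies the strand-specific conversion rule", {
  # ref T with 5 C among 10 forward reads: a plus-strand site of value 5
  p1 <- pile("chrA", c(100L, 100L), "T", "+", c("C", "T"), c(5L, 5L))
  s1 <- detect_crosslink_sites(p1)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$strand, "+")
  expect_equal(s1$converted_reads, 5)
  expect_equal(s1$total_reads, 10)

  # C conversions carried only by reverse-strand reads: no plus site
  p2 <- pile("chrA", c(100L, 100L), "T", "-", c("C", "T"), c(5L, 5L))
  expect_equal(nrow(detect_crosslink_sites(p2)), 0L)

  # non-T/non-A reference: never a site
  p3 <- pile("chrA", c(100L, 100L), "G", "+", c("C", "G"), c(8L, 8L))
  expect_equal(nrow(detect_crosslink_sites(p3)), 0L)

  # mirrored minus-strand rule: ref A, G conversions on reverse reads
  p4 <- pile("chrA", c(200L, 200L), "A", "-", c("G", "A"), c(4L, 10L))
  s4 <- detect_crosslink_sites(p4)
  expect_equal(s4$strand, "-")
  expect_equal(s4$converted_reads, 4)
})

test_that("detection thresholds gate depth, count and fraction", {
  cfg <- occupancy_config()
  # depth 9 < 10: rejected even with strong conversion
  expect_equal(nrow(detect_crosslink_sites(
    pile("chrA", c(10L, 10L), "T", "+", c("C", "T"), c(5L, 4L)), cfg)), 0L)
  # single converted read < 2: rejected
  expect_equal(nrow(detect_crosslink_sites(
    pile("chrA", c(10L, 10L), "T", "+", c("C", "T"), c(1L, 19L)), cfg)), 0L)
  # fraction below threshold: 2/300 < 0.01
  expect_equal(nrow(detect_crosslink_sites(
    pile("chrA", c(10L, 10L), "T", "+", c("C", "T"), c(2L, 298L)), cfg)),
    0L)
  # exactly at every threshold: 2 converted, depth 200, fraction 0.01
  expect_equal(nrow(detect_crosslink_sites(
    pile("chrA", c(10L, 10L), "T", "+", c("C", "T"), c(2L, 198L)), cfg)),
    1L)
})

test_that("unsorted pileups are rejected", {
  p <- pile("chrA", c(200L, 100L), "T", "+", "C", c(5L, 5L))
  expect_error(detect_crosslink_sites(p), "sorted")
})

test_that("site calling agrees with a per-record reference on random pileups", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 30L
    p <- pile(sample(names(genomeP), n, replace = TRUE),
              sample.int(500L, n, replace = TRUE),
              sample(c("A", "C", "G", "T"), n, replace = TRUE),
              sample(c("+", "-"), n, replace = TRUE),
              sample(c("A", "C", "G", "T"), n, replace = TRUE),
              sample(0:40, n, replace = TRUE))
    p <- p[order(p$chrom, p$pos), ]
    rownames(p) <- NULL
    expect_identical(detect_crosslink_sites(p), oracle_crosslink_sites(p))
  }
})

test_that("crosslink tracks carry converted counts scaled to one million", {
  sites <- data.frame(chrom = "chrA", pos = c(50L, 60L), strand = "+",
                      converted_reads = c(1, 3), total_reads = c(10, 12),
                      value = c(1, 3), stringsAsFactors = FALSE)
  tr <- crosslink_track(sites, genomeP)
  expect_equal(track_value(tr, "chrA", 50, "+"), 250000)
  expect_equal(track_value(tr, "chrA", 60, "+"), 750000)
  expect_equal(track_mass(tr), 1e6, tolerance = 1e-6)

  dup <- rbind(sites, sites[1, ])
  expect_error(crosslink_track(dup, genomeP), "duplicate")
  expect_error(crosslink_track(sites[0, ], genomeP), "empty track")
})

test_that("smoothing is a fixed point on constant tracks and floors zeros", {
  const <- coverage_track(
    lapply(genomeP, function(L) S4Vectors::Rle(4, L)),
    lapply(genomeP, function(L) S4Vectors::Rle(0, L)), genomeP)
  sm <- smooth_nascent(const)
  # interior values are exactly the constant (truncation only affects ends
  # where the window still sees only the constant)
  expect_equal(unique(dense_values(sm, "chrA", "+")), 4)
  # an all-zero chromosome smooths to exactly the pseudocount
  expect_equal(unique(dense_values(sm, "chrA", "-")), 0.1)

  # spike of 51 among zeros: interior windows containing it average
  # (51 + 50 * 0.1) / 51
  spike <- track_from_positions(
    data.frame(chrom = "chrA", pos = 1000L, strand = "+", value = 51),
    genomeP)
  sms <- smooth_nascent(spike)
  expect_equal(track_value(sms, "chrA", 1000, "+"), (51 + 50 * 0.1) / 51)
  expect_equal(track_value(sms, "chrA", 1025, "+"), (51 + 50 * 0.1) / 51)
  expect_equal(track_value(sms, "chrA", 1026, "+"), 0.1)
  expect_true(all(dense_values(sms, "chrA", "+") > 0))

  expect_error(occupancy_config(smoothing_window = 50), "odd")
})

test_that("smoothing truncates windows at chromosome ends", {
  # spike at position 0: the window at position 0 spans only [0, 25]
  spike <- track_from_positions(
    data.frame(chrom = "chrA", pos = 0L, strand = "+", value = 26),
    genomeP)
  sm <- smooth_nascent(spike)
  expect_equal(track_value(sm, "chrA", 0, "+"), (26 + 25 * 0.1) / 26)
})

test_that("occupancy is the per-position quotient, sparse in the numerator", {
  parclip <- track_from_positions(
    data.frame(chrom = "chrA", pos = c(100L, 200L), strand = "+",
               value = c(10, 6)), genomeP)
  nascent <- coverage_track(
    lapply(genomeP, function(L) S4Vectors::Rle(2, L)),
    lapply(genomeP, function(L) S4Vectors::Rle(2, L)), genomeP)
  occ <- normalized_occupancy(parclip, nascent)
  expect_equal(track_value(occ, "chrA", 100, "+"), 5)
  expect_equal(track_value(occ, "chrA", 200, "+"), 3)
  expect_equal(track_value(occ, "chrA", 150, "+"), 0)

  # random sparse tracks match a dense elementwise quotient
  set.seed(19)
  df <- data.frame(chrom = sample(names(genomeP), 30L, replace = TRUE),
                   pos = sample.int(1000L, 30L) - 1L,
                   strand = sample(c("+", "-"), 30L, replace = TRUE),
                   value = stats::rpois(30L, 8) + 1)
  df <- df[!duplicated(df[c("chrom", "pos", "strand")]), ]
  sp <- track_from_positions(df, genomeP)
  sm <- smooth_nascent(simulated_nascent <- coverage_track(
    lapply(genomeP, function(L) S4Vectors::Rle(stats::runif(L, 0.5, 3))),
    lapply(genomeP, function(L) S4Vectors::Rle(stats::runif(L, 0.5, 3))),
    genomeP))
  occ2 <- normalized_occupancy(sp, sm)
  for (chr in names(genomeP)) for (s in c("+", "-")) {
    p <- dense_values(sp, chr, s); d <- dense_values(sm, chr, s)
    expect_equal(dense_values(occ2, chr, s), ifelse(p != 0, p / d, 0))
  }

  # unsmoothed (zero-bearing) denominator under signal is an error
  zeros <- coverage_track(GenomicRanges::GRanges(),
                          GenomicRanges::GRanges(), genomeP)
  expect_error(normalized_occupancy(parclip, zeros), "smoothed")
})

test_that("interval occupancy sums the track and matches interval_signal", {
  occ <- track_from_positions(
    data.frame(chrom = "chrA", pos = c(100L, 120L), strand = "+",
               value = c(5, 2.5)), genomeP)
  iv <- genomic_interval("chrA", 90, 130, "+")
  expect_equal(occupancy_over_interval(occ, iv), 7.5)
  expect_equal(occupancy_over_interval(occ, iv),
               interval_signal(occ, iv, "same"))
  expect_equal(occupancy_over_interval(occ, iv, aggregate = "mean"),
               7.5 / 40)
  expect_equal(occupancy_over_interval(
    occ, genomic_interval("chrA", 500, 600, "+")), 0)
})

test_that("pileup TSV round trips through the reader", {
  p <- pile("chrA", c(100L, 100L), "T", "+", c("C", "T"), c(5L, 5L))
  path <- tempfile(fileext = ".tsv")
  writeLines("# seed: 1", path)
  suppressWarnings(utils::write.table(p, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = FALSE,
                                      append = TRUE))
  expect_equal(read_pileup(path), p)
})
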