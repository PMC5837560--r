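genome2 <- c(chrA = 10000L, chrB = 10000L)

reads_df <- function(chrom, start, end, strand, mapq = 30L, mapped = TRUE) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             mapq = mapq, mapped = mapped, stringsAsFactors = FALSE)
}

test_that("MAPQ filtering drops reads at the threshold and below", {
  reads <- reads_df("chrA", c(10L, 20L, 30L), c(60L, 70L, 80L), "+",
                    mapq = c(10L, 11L, 0L))
  kept <- filter_alignments(reads)
  expect_equal(kept$start, 20L)   # MAPQ 10 dropped, 11 kept, 0 dropped
})

test_that("unmapped reads and reads touching exclusion regions are dropped", {
  excl <- annotation_set("tRNA1", "other", "chrA", 100L, 200L, "+",
                         genome2)
  cfg <- alignment_filter_config(exclusion_regions = excl)
  reads <- reads_df("chrA",
                    c(50L, 160L, 199L, 200L, 500L),
                    c(99L, 210L, 240L, 250L, 550L),
                    c("+", "-", "+", "+", "+"),
                    mapped = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  kept <- filter_alignments(reads, cfg)
  # 1 bp overlap drops (either strand); adjacency at 200 does not; the
  # unmapped read goes regardless of MAPQ
  expect_equal(kept$start, c(50L, 200L))
})

test_that("a planted filtering cohort survives at the expected count", {
  set.seed(31)
  n <- 100L
  mapq <- rep(30L, n); mapq[1:30] <- sample(0:10, 30L, replace = TRUE)
  start <- c(rep(5000L, 90L), rep(150L, 10L))[sample(n)]
  excl <- annotation_set("sn1", "other", "chrA", 100L, 300L, "+", genome2)
  reads <- reads_df("chrA", start, start + 50L, "+", mapq = mapq)
  kept <- filter_alignments(reads,
                            alignment_filter_config(exclusion_regions = excl))
  # per-read oracle
  expect_equal(nrow(kept),
               sum(mapq > 10L & start >= 300L))
})

test_that("missing MAPQ is treated as zero and dropped with a message", {
  reads <- reads_df("chrA", c(10L, 20L), c(60L, 70L), "+",
                    mapq = c(NA, 30L))
  expect_message(kept <- filter_alignments(reads), "missing MAPQ")
  expect_equal(kept$start, 20L)
})

test_that("5' coverage places one tag per read at the strand-aware 5' end", {
  reads <- reads_df("chrA", rep(100L, 4L), rep(150L, 4L),
                    c("+", "-", "-", "-"))
  tr <- five_prime_coverage(reads, genome2)
  expect_equal(track_value(tr, "chrA", 100, "+"), 1)
  expect_equal(track_value(tr, "chrA", 149, "-"), 3)
  expect_equal(track_mass(tr), nrow(reads))
  expect_error(five_prime_coverage(reads_df("chrA", 9990L, 10050L, "-"),
                                   genome2),
               "outside chromosome bounds")
})

test_that("SAM input is read through Rsamtools with spliced spans resolved", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrA\tLN:10000",
    "r1\t0\tchrA\t101\t40\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchrA\t201\t40\t20M10N20M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r4\t0\tchrA\t301\t5\t50M\t*\t0\t0\t*\t*"), sam)
  reads <- read_alignments(sam)
  expect_equal(nrow(reads), 4L)
  expect_equal(reads$start[1], 100L)
  expect_equal(reads$end[2], 250L)      # 20M10N20M spans 50 reference bp
  expect_false(reads$mapped[3])
  kept <- filter_alignments(reads)
  expect_equal(nrow(kept), 2L)          # unmapped and MAPQ 5 removed
  tr <- five_prime_coverage(kept, genome2)
  expect_equal(track_value(tr, "chrA", 100, "+"), 1)
  expect_equal(track_value(tr, "chrA", 249, "-"), 1)  # 5' of minus read
})

test_that("per-million normalization scales to the target mass", {
  df <- data.frame(chrom = "chrA", pos = c(10L, 20L), strand = c("+", "-"),
                   value = c(5, 15))
  tr <- normalize_cpm(track_from_positions(df, genome2))
  expect_equal(track_value(tr, "chrA", 10, "+"), 250000)
  expect_equal(track_value(tr, "chrA", 20, "-"), 750000)
  expect_equal(track_mass(tr), 1e6, tolerance = 1e-6)
  expect_true(tr$normalized)

  # idempotent up to floating tolerance
  tr2 <- normalize_cpm(tr)
  expect_equal(dense_values(tr2, "chrA", "+"), dense_values(tr, "chrA", "+"),
               tolerance = 1e-12)

  empty <- coverage_track(GenomicRanges::GRanges(),
                          GenomicRanges::GRanges(), genome2)
  expect_error(normalize_cpm(empty), "empty track")
})

test_that("track subtraction matches a dense oracle and inverts by addition", {
  set.seed(13)
  mk <- function() {
    n <- 40L
    df <- data.frame(chrom = sample(names(genome2), n, replace = TRUE),
                     pos = sample.int(10000L, n) - 1L,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     value = stats::rpois(n, 5))
    df <- df[!duplicated(df[c("chrom", "pos", "strand")]), ]
    track_from_positions(df, genome2)
  }
  a <- mk(); b <- mk()
  d <- subtract_tracks(a, b)
  expect_true(d$allow_negative)
  for (chr in names(genome2)) for (s in c("+", "-")) {
    expect_equal(dense_values(d, chr, s),
                 dense_values(a, chr, s) - dense_values(b, chr, s))
    # d + b recovers a per position
    expect_equal(dense_values(d, chr, s) + dense_values(b, chr, s),
                 dense_values(a, chr, s), tolerance = 1e-9)
  }

  # self-subtraction is all-zero; zero-fill semantics for absent positions
  z <- subtract_tracks(a, a)
  expect_equal(track_mass(z), 0)
  one <- track_from_positions(
    data.frame(chrom = "chrA", pos = 7L, strand = "+", value = 3), genome2)
  other <- track_from_positions(
    data.frame(chrom = "chrA", pos = 9L, strand = "+", value = 2), genome2)
  d2 <- subtract_tracks(one, other)
  expect_equal(track_value(d2, "chrA", 7, "+"), 3)
  expect_equal(track_value(d2, "chrA", 9, "+"), -2)

  expect_error(subtract_tracks(a, coverage_track(
    GenomicRanges::GRanges(), GenomicRanges::GRanges(), c(chrA = 5000L))),
    "genome mismatch")
})

test_that("interval signal resolves strands and is additive over partitions", {
  df <- data.frame(chrom = "chrA", pos = c(10L, 11L, 11L),
                   strand = c("+", "+", "-"), value = c(3, 4, 9))
  tr <- track_from_positions(df, genome2)
  iv_plus <- genomic_interval("chrA", 10, 12, "+")
  iv_minus <- genomic_interval("chrA", 10, 12, "-")
  expect_equal(interval_signal(tr, iv_plus, "same"), 7)
  expect_equal(interval_signal(tr, iv_plus, "opposite"), 9)
  expect_equal(interval_signal(tr, iv_minus, "same"), 9)
  expect_equal(interval_signal(tr, iv_minus, "opposite"), 7)
  expect_equal(interval_signal(tr, genomic_interval("chrA", 500, 600, "+")),
               0)
  expect_error(interval_signal(tr, genomic_interval("chrA", 9990, 10050,
                                                    "+")),
               "out of bounds")

  # additivity over a partition
  whole <- genomic_interval("chrA", 0, 100, "+")
  left <- genomic_interval("chrA", 0, 11, "+")
  right <- genomic_interval("chrA", 11, 100, "+")
  expect_equal(interval_signal(tr, whole),
               interval_signal(tr, left) + interval_signal(tr, right))
})
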