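test_that("genome construction validates and exposes its size", {
  g <- make_genome(c("chr1", "chr2"), c(10000, 5000))
  expect_equal(genome_size(g), 15000)
  expect_error(make_genome(c("chr1", "chr1"), c(10, 10)), "unique")
  expect_error(make_genome("chr1", 0), "positive")
  expect_error(interval_set("chrX", 0, 10, g), "unknown chromosome")
  expect_error(interval_set("chr1", 50, 50, g), "start < end")
  expect_error(interval_set("chr1", 0, 10001, g), "exceeds")
})

test_that("BED-family readers parse dialects and apply the chromosome policy", {
  g <- make_genome("chr1", 1000)
  bed3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", bed3)
  x <- read_bed(bed3, g, "bed3")
  expect_equal(as_bed_frame(x), data.frame(chrom = "chr1", start = 0, end = 100))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t10\t210\tpeak1\t960\t.\t5.5\t12.0\t9.1\t100", np)
  y <- read_bed(np, g, "narrowPeak")
  expect_equal(as_bed_frame(y)$start, 10)
  expect_equal(S4Vectors::mcols(y)$name, "peak1")
  expect_equal(S4Vectors::mcols(y)$signalValue, 5.5)
  expect_equal(S4Vectors::mcols(y)$peak, 100L)

  unk <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t50", "chrUn_gl000220\t0\t50"), unk)
  expect_warning(z <- read_bed(unk, g, "bed3"), "dropped")
  expect_equal(length(z), 1L)
  expect_error(read_bed(unk, g, "bed3", on_unknown_chrom = "strict"),
               "unknown chromosome")
})

test_that("BED round-trips through the writer", {
  g <- toy_genome()
  x <- interval_set(c("chr1", "chr2"), c(5, 100), c(50, 900), g,
                    name = c("a", "b"), score = c(1, 2))
  f <- tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f, g, "bed6")
  expect_equal(as_bed_frame(y)[, 1:3], as_bed_frame(x)[, 1:3])
  expect_equal(S4Vectors::mcols(y)$name, c("a", "b"))
})

test_that("merge coalesces overlapping and abutting intervals", {
  g <- make_genome("chr1", 1000)
  m1 <- merge_intervals(interval_set("chr1", c(0, 50), c(100, 150), g))
  expect_equal(as_bed_frame(m1)[, 1:3],
               data.frame(chrom = "chr1", start = 0, end = 150))
  m2 <- merge_intervals(interval_set("chr1", c(0, 100), c(100, 200), g))
  expect_equal(as_bed_frame(m2)$end, 200)
})

test_that("intersect matches hand examples and errors on genome mismatch", {
  g <- make_genome("chr1", 1000)
  a <- interval_set("chr1", 0, 100, g)
  b <- interval_set("chr1", 50, 150, g)
  expect_equal(as_bed_frame(intersect_intervals(a, b))[, 1:3],
               data.frame(chrom = "chr1", start = 50, end = 100))
  d <- interval_set("chr1", 500, 600, g)
  expect_equal(length(intersect_intervals(a, d)), 0L)
  g2 <- make_genome("chr1", 2000)
  expect_error(intersect_intervals(a, interval_set("chr1", 0, 10, g2)),
               "different genomes")
})

test_that("control subtraction drops whole overlapping peaks", {
  g <- make_genome("chr1", 1000)
  peaks <- interval_set("chr1", c(0, 200), c(100, 300), g)
  ctrl <- interval_set("chr1", 250, 260, g)
  out <- subtract_control(peaks, ctrl)
  expect_equal(as_bed_frame(out)[, 1:3],
               data.frame(chrom = "chr1", start = 0, end = 100))
  expect_equal(length(subtract_control(peaks, peaks[0])), 2L)
  whole <- interval_set("chr1", 0, 1000, g)
  expect_equal(length(subtract_control(peaks, whole)), 0L)
  expect_error(subtract_control(peaks, ctrl, min_overlap_bp = 0), ">= 1")
})

test_that("consensus union emits merged union spans of overlapping pairs", {
  g <- make_genome("chr1", 1000)
  r1 <- interval_set("chr1", c(0, 200), c(100, 300), g)
  r2 <- interval_set("chr1", c(50, 400), c(150, 500), g)
  expect_equal(as_bed_frame(consensus_union(r1, r2))[, 1:3],
               data.frame(chrom = "chr1", start = 0, end = 150))
  same <- interval_set("chr1", 10, 20, g)
  expect_equal(as_bed_frame(consensus_union(same, same))[, 1:3],
               data.frame(chrom = "chr1", start = 10, end = 20))
  expect_equal(length(consensus_union(r1, interval_set("chr1", 600, 700, g))),
               0L)
  # alternative coordinate modes
  expect_equal(as_bed_frame(consensus_union(r1, r2, mode = "intersection"))[, 1:3],
               data.frame(chrom = "chr1", start = 50, end = 100))
  expect_equal(as_bed_frame(consensus_union(r1, r2, mode = "rep1"))[, 1:3],
               data.frame(chrom = "chr1", start = 0, end = 100))
})

test_that("overlap counts and coverage fraction match hand examples", {
  g <- make_genome("chr1", 10000)
  q <- interval_set("chr1", c(0, 2000, 4000), c(100, 2100, 4100), g)
  ref <- interval_set("chr1", 2050, 2060, g)
  expect_equal(unname(overlap_counts(q, ref)), c(1, 3))
  expect_equal(unname(overlap_counts(q, q)), c(3, 3))
  expect_equal(coverage_fraction(interval_set("chr1", 0, 2000, g), g), 0.2)
  expect_equal(coverage_fraction(q[0], g), 0)
})

test_that("interval algebra agrees with the per-base oracle on random sets", {
  g <- toy_genome()
  set.seed(42)
  for (rep in 1:60) {
    a_df <- rand_intervals(g, sample.int(40, 1))
    b_df <- rand_intervals(g, sample.int(40, 1))
    a <- frame_to_iset(a_df, g); b <- frame_to_iset(b_df, g)
    minov <- sample(c(1, 5, 50), 1)

    expect_same_intervals(merge_intervals(a), oracle_merge(a_df, g))
    expect_same_intervals(intersect_intervals(a, b),
                          oracle_intersect(a_df, b_df, g))
    sub <- subtract_control(a, b, minov)
    sub_or <- oracle_subtract(a_df, b_df, g, minov)
    expect_same_intervals(merge_intervals(sub), oracle_merge(sub_or, g))
    expect_same_intervals(consensus_union(a, b, minov),
                          oracle_consensus(a_df, b_df, g, minov))
    expect_equal(unname(overlap_counts(a, b, minov)),
                 oracle_overlap_counts(a_df, b_df, g, minov))
    expect_equal(coverage_fraction(a, g), oracle_coverage(a_df, g))
  }
})

test_that("algebraic identities hold", {
  g <- toy_genome()
  set.seed(7)
  for (rep in 1:10) {
    a <- frame_to_iset(rand_intervals(g, 30), g)
    b <- frame_to_iset(rand_intervals(g, 30), g)
    # merge idempotent
    expect_equal(merged_frame(merge_intervals(merge_intervals(a))),
                 merged_frame(merge_intervals(a)))
    # intersect commutative
    expect_equal(merged_frame(intersect_intervals(a, b)),
                 merged_frame(intersect_intervals(b, a)))
    # consensus symmetric; consensus(a, a) = merge(a)
    expect_equal(merged_frame(consensus_union(a, b)),
                 merged_frame(consensus_union(b, a)))
    expect_equal(merged_frame(consensus_union(a, a)),
                 merged_frame(merge_intervals(a)))
    # subtraction identities
    expect_equal(length(subtract_control(a, a[0])), length(a))
    am <- merge_intervals(a)
    expect_equal(length(subtract_control(am, am)), 0L)
  }
})
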