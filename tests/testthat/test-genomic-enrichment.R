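test_that("subtelomeric windows clip, merge, and cover min(2w, L)", {
  g <- make_genome("chr1", 10000)
  w <- subtelomeric_windows(g, 1000)
  expect_equal(as_bed_frame(w)[, 1:3],
               data.frame(chrom = c("chr1", "chr1"), start = c(0, 9000),
                          end = c(1000, 10000)))
  short <- make_genome("chrS", 1500)
  ws <- subtelomeric_windows(short, 1000)
  expect_equal(as_bed_frame(ws)[, 1:3],
               data.frame(chrom = "chrS", start = 0, end = 1500))
  expect_equal(as_bed_frame(subtelomeric_windows(g, 1000, ends = "left"))$end,
               1000)
  # coverage invariant over a mixed genome
  g3 <- make_genome(c("c1", "c2", "c3"), c(10000, 1800, 900))
  w3 <- subtelomeric_windows(g3, 1000)
  covered <- sum(as.numeric(GenomicRanges::width(w3)))
  expect_equal(covered, sum(pmin(2 * 1000, c(10000, 1800, 900))))
})

test_that("fold enrichment matches hand-computed fractions", {
  g <- make_genome("chr1", 10000)
  regions <- subtelomeric_windows(g, 1000)   # 2000 bp of 10 kb -> f_exp 0.2
  # 6 peaks with midpoints in the windows, 4 outside
  mids <- c(100, 300, 500, 9100, 9300, 9500, 3000, 4000, 5000, 6000)
  peaks <- interval_set("chr1", mids - 50, mids + 50, g)
  r <- fold_enrichment(peaks, regions, g)
  expect_equal(r$f_obs, 0.6)
  expect_equal(r$f_exp, 0.2)
  expect_equal(r$fold, 3.0)
  # uniform tiling: midpoints at 500, 1500, ..., 9500 -> fold 1
  mids2 <- seq(500, 9500, by = 1000)
  peaks2 <- interval_set("chr1", mids2 - 50, mids2 + 50, g)
  expect_equal(fold_enrichment(peaks2, regions, g)$fold, 1.0)
  expect_error(fold_enrichment(peaks[0], regions, g), "empty")
  expect_error(fold_enrichment(peaks, regions[0], g), "regions empty")
})

test_that("permutation p-values respect the add-one rule and the seed", {
  g <- make_genome("chr1", 10000)
  regions <- subtelomeric_windows(g, 1000)
  peaks <- interval_set("chr1", c(3000, 5000), c(3100, 5100), g)
  r1 <- permutation_test(peaks, regions, g, n_perm = 1, seed = 1)
  expect_equal(r1$p_perm, 1.0)  # null >= observed(0) always
  r2 <- permutation_test(peaks, regions, g, n_perm = 99, seed = 5)
  expect_gte(r2$p_perm, 1 / 100)
  r3 <- permutation_test(peaks, regions, g, n_perm = 99, seed = 5)
  expect_identical(r2$null_counts, r3$null_counts)  # seeded determinism
  r4 <- permutation_test(peaks, regions, g, n_perm = 99, seed = 6)
  expect_false(identical(r2$null_counts, r4$null_counts))
})

test_that("planted subtelomeric enrichment is detected by the permutation test", {
  g <- make_genome(paste0("chr", 1:4), c(80000, 60000, 50000, 30000))
  sim <- simulate_peaks(g, 500, length_mean = 200, subtel_fold = 5,
                        window_bp = 1000, seed = 11)
  r <- permutation_test(sim$peaks, sim$windows, g, n_perm = 199, seed = 12)
  expect_lte(r$p_perm, 0.01)
  expect_lt(abs(r$fold / 5 - 1), 0.25)
  expect_lt(r$p_binom, 0.01)
  # genome-wide placement is also available and seeded
  r2 <- permutation_test(sim$peaks, sim$windows, g, n_perm = 49, seed = 1,
                         placement = "genome_wide")
  expect_lte(r2$p_perm, 0.02)
})

test_that("fisher_exact reproduces worked exact values", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
})

test_that("fisher_exact agrees with stats::fisher.test and the lchoose oracle", {
  set.seed(3)
  for (i in 1:150) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
    expect_equal(fisher_exact(tab),
                 oracle_fisher_two_sided(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab, "greater"),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(fisher_exact(tab, "less"),
                 fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("feature annotation flags a saturated feature and not a null one", {
  g <- toy_genome()
  set.seed(9)
  peaks <- frame_to_iset(rand_intervals(g, 200, max_len = 100), g)
  half <- interval_set(c("chr1", "chr2", "chr3"), c(0, 0, 0),
                       c(5000, 3000, 1500), g)  # 50% of the genome
  rep <- annotate_features(peaks, list(self = peaks, half = half),
                           n_shuffle = 10, seed = 21)
  self_row <- rep[rep$feature == "self", ]
  expect_equal(self_row$f_obs, 1.0)
  expect_gt(self_row$fold, 1)
  expect_lt(self_row$fisher_p, 1e-6)
  half_row <- rep[rep$feature == "half", ]
  expect_lt(abs(half_row$fold - 1), 0.2)
  expect_gt(half_row$fisher_p, 0.05)
  expect_warning(
    annotate_features(peaks, list(ok = half, gone = NULL),
                      n_shuffle = 2, seed = 1), "missing")
})

test_that("TSS point features are expanded by the flank before annotation", {
  g <- make_genome("chr1", 100000)
  tss <- interval_set("chr1", 50000, 50001, g)
  peaks <- interval_set("chr1", c(49500, 80000), c(49600, 80100), g)
  rep <- annotate_features(peaks, list(TSS = tss), tss_flank_bp = 2000,
                           n_shuffle = 5, seed = 2)
  expect_equal(rep$n_obs, 1)  # only the peak within 2 kb of the TSS
})

test_that("co-occurrence handles saturation, disjoint marks, and planted odds", {
  g <- toy_genome()
  set.seed(31)
  peaks <- frame_to_iset(rand_intervals(g, 300, max_len = 60), g)
  whole <- genome_ranges(g)
  r <- cooccurrence(peaks, whole, whole, g, n_shuffle = 2, seed = 1)
  expect_equal(r$fraction, 1.0)
  mkA <- interval_set("chr1", 0, 5000, g)
  mkB <- interval_set("chr2", 0, 5000, g)
  inA <- interval_set("chr1", c(100, 1000), c(200, 1100), g)
  expect_equal(cooccurrence(inA, mkA, mkB, g, n_shuffle = 2, seed = 1)$n_both,
               0)
  expect_error(cooccurrence(peaks, mkA[0], mkB, g, n_shuffle = 2, seed = 1),
               "empty mark")
  g2 <- simulate_genome(4, 2500000)
  sim <- simulate_peaks(g2, 1000, length_mean = 60, subtel_fold = 1,
                        window_bp = 500, seed = 41, constant_length = TRUE)
  mt <- suppressWarnings(
    simulate_mark_tracks(g2, sim$peaks, odds_ratio = 4,
                         mark_density = 0.2, seed = 42))
  rc <- cooccurrence(sim$peaks, mt$markA, mt$markB, g2, n_shuffle = 10,
                     seed = 43)
  expect_lt(rc$fisher_p, 0.01)
  expect_gt(rc$fold, 1)
})
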