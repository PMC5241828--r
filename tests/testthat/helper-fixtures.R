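# Shared end-to-end fixtures.

# two replicate peak files resampling one set of true binding sites
# (dropout + coordinate jitter), the regime in which consensus sites
# reflect the truth set and its planted subtelomeric fold
sim_replicate_beds <- function(dir, fold, seed, n = 400) {
  g <- simulate_genome(3, c(300000, 250000, 200000))
  sizes <- file.path(dir, "toy.chrom.sizes")
  write.table(data.frame(GenomeInfoDb::seqnames(g),
                         GenomeInfoDb::seqlengths(g)),
              sizes, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  truth <- simulate_peaks(g, n, length_mean = 150, subtel_fold = fold,
                          window_bp = 2000, seed = seed)
  jitter_rep <- function(rep_seed) {
    df <- as_bed_frame(truth$peaks)
    set.seed(rep_seed)
    df <- df[runif(nrow(df)) < 0.85, ]          # peak-calling dropout
    sh <- round(runif(nrow(df), -40, 40))       # boundary jitter
    L <- GenomeInfoDb::seqlengths(g)[df$chrom]
    s <- pmax(0, pmin(df$start + sh, L - 1))
    e <- pmax(s + 1, pmin(df$end + sh, L))
    interval_set(df$chrom, s, e, g)
  }
  b1 <- file.path(dir, "rep1.bed"); b2 <- file.path(dir, "rep2.bed")
  write_bed(jitter_rep(seed + 1), b1)
  write_bed(jitter_rep(seed + 2), b2)
  list(genome = g, sizes = sizes, rep1 = b1, rep2 = b2)
}

sim_position_condition <- function(quantiles, n_img, seed) {
  lapply(seq_len(n_img), function(i) {
    sim <- simulate_nucleus_image(
      150, 120, list(list(cx = 75, cy = 60, a = 60, b = 45)),
      nucleoplasm = 100,
      spots = list(n = length(quantiles), sigma = 2, amplitude = 300,
                   radial_quantile = quantiles),
      seed = seed + i)
    list(mask = sim$masks, points = sim$truth$spots[, c("x", "y")])
  })
}

# split one large iid peak sample into independent equal-size replicates;
# the sample comes back canonically sorted, so assign groups by a random
# permutation (fixed seed), not by consecutive blocks of sorted positions
split_peaks <- function(peaks, n_rep, seed = 1L) {
  k <- length(peaks) / n_rep
  idx <- local({ set.seed(seed); sample.int(length(peaks)) })
  lapply(seq_len(n_rep), function(r)
    peaks[idx[seq.int((r - 1) * k + 1, r * k)]])
}
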