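# Brute-force oracles, independent of the interval machinery under test:
# interval sets are expanded to per-base logical vectors with plain loops,
# set algebra is boolean algebra on those vectors, and exact-test p-values
# are enumerated from binomial coefficients.

# one logical vector per chromosome, TRUE where covered
base_vectors <- function(df, genome) {
  L <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(L, function(n) logical(n))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (df$end[i] > df$start[i])
      out[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  out
}

# logical vectors back to a 0-based half-open data frame (merged form)
bases_to_frame <- function(bv) {
  rows <- NULL
  for (ch in names(bv)) {
    r <- rle(bv[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      rows <- rbind(rows, data.frame(chrom = ch, start = starts[keep],
                                     end = ends[keep]))
  }
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  rows[order(rows$chrom, rows$start), , drop = FALSE]
}

oracle_merge <- function(df, genome) bases_to_frame(base_vectors(df, genome))

oracle_intersect <- function(a, b, genome) {
  va <- base_vectors(a, genome); vb <- base_vectors(b, genome)
  bases_to_frame(mapply(function(x, y) x & y, va, vb, SIMPLIFY = FALSE))
}

# per-peak base overlap with a control set
oracle_overlap_bp <- function(peak_row, vb) {
  sum(vb[[peak_row$chrom]][(peak_row$start + 1):peak_row$end])
}

oracle_subtract <- function(peaks, control, genome, minov = 1) {
  vb <- base_vectors(control, genome)
  keep <- vapply(seq_len(nrow(peaks)), function(i)
    oracle_overlap_bp(peaks[i, ], vb) < minov, logical(1))
  peaks[keep, , drop = FALSE]
}

oracle_consensus <- function(r1, r2, genome, minov = 1) {
  spans <- NULL
  for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
    if (r1$chrom[i] != r2$chrom[j]) next
    ov <- min(r1$end[i], r2$end[j]) - max(r1$start[i], r2$start[j])
    if (ov >= minov)
      spans <- rbind(spans, data.frame(chrom = r1$chrom[i],
                                       start = min(r1$start[i], r2$start[j]),
                                       end = max(r1$end[i], r2$end[j])))
  }
  if (is.null(spans))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  oracle_merge(spans, genome)
}

oracle_overlap_counts <- function(query, reference, genome, minov = 1) {
  vb <- base_vectors(reference, genome)
  n <- sum(vapply(seq_len(nrow(query)), function(i)
    oracle_overlap_bp(query[i, ], vb) >= minov, logical(1)))
  c(n, nrow(query))
}

oracle_coverage <- function(df, genome) {
  v <- base_vectors(df, genome)
  sum(vapply(v, sum, numeric(1))) / sum(GenomeInfoDb::seqlengths(genome))
}

# random interval set on a genome, as a 0-based data frame
rand_intervals <- function(genome, n, max_len = 500) {
  L <- GenomeInfoDb::seqlengths(genome)
  ch <- sample(names(L), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  len <- pmin(len, L[ch])
  s <- floor(runif(n) * (L[ch] - len + 1))
  data.frame(chrom = ch, start = s, end = s + len,
             stringsAsFactors = FALSE)
}

frame_to_iset <- function(df, genome) {
  interval_set(df$chrom, df$start, df$end, genome)
}

merged_frame <- function(gr) {
  df <- as_bed_frame(merge_intervals(gr))
  rownames(df) <- NULL
  df[order(df$chrom, df$start), c("chrom", "start", "end"), drop = FALSE]
}

expect_same_intervals <- function(gr, df_oracle) {
  got <- merged_frame(gr)
  want <- df_oracle[, c("chrom", "start", "end"), drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  want$chrom <- as.character(want$chrom)
  want$start <- as.numeric(want$start); want$end <- as.numeric(want$end)
  got$start <- as.numeric(got$start); got$end <- as.numeric(got$end)
  expect_equal(got, want)
}

# exact two-sided hypergeometric p via binomial coefficients (lchoose),
# independent of dhyper
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  ltot <- lchoose(m + n, k)
  lp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(n, k - x) - ltot, numeric(1))
  p <- exp(lp)
  pa <- p[(lo:hi) == a]
  min(1, sum(p[p <= pa * (1 + 1e-7)]))
}

toy_genome <- function(lens = c(chr1 = 10000, chr2 = 6000, chr3 = 3000)) {
  make_genome(names(lens), unname(lens))
}
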