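# Genomic-interval enrichment: subtelomeric windows, fold enrichment with
# permutation and binomial nulls, feature annotation, mark co-occurrence.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so
#' seeded package functions never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an explicit integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Subtelomeric windows of a genome
#'
#' Defines subtelomeric regions as fixed-width windows adjacent to each
#' chromosome terminus (default 500 kb, both ends). Windows are clipped to
#' the chromosome and merged when the chromosome is shorter than twice the
#' window, so base coverage per chromosome is `min(2 * window_bp, L)` for
#' `ends = "both"`.
#'
#' @param genome A `Seqinfo` genome.
#' @param window_bp Window width in bp (> 0); default 500,000.
#' @param ends Which termini count: `"both"` (default), `"left"`, `"right"`.
#' @return Merged `GRanges` of subtelomeric windows.
#' @export
subtelomeric_windows <- function(genome, window_bp = 500000L,
                                 ends = c("both", "left", "right")) {
  ends <- match.arg(ends)
  if (window_bp <= 0) stop("window_bp must be > 0")
  L <- as.numeric(GenomeInfoDb::seqlengths(genome))
  nm <- GenomeInfoDb::seqnames(genome)
  chrom <- character(0); s <- numeric(0); e <- numeric(0)
  if (ends %in% c("both", "left")) {
    chrom <- c(chrom, nm); s <- c(s, rep(0, length(nm)))
    e <- c(e, pmin(window_bp, L))
  }
  if (ends %in% c("both", "right")) {
    chrom <- c(chrom, nm); s <- c(s, pmax(0, L - window_bp))
    e <- c(e, L)
  }
  merge_intervals(interval_set(chrom, s, e, genome))
}

peak_midpoints <- function(peaks) {
  # midpoint of [start0, end0): floor((start0 + end0) / 2), as a width-1 range
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  mid0 <- floor((s0 + e0) / 2)
  GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                         IRanges::IRanges(mid0 + 1L, width = 1L),
                         seqinfo = GenomeInfoDb::seqinfo(peaks))
}

count_in_regions <- function(peaks, regions,
                             membership = c("midpoint", "any_overlap")) {
  membership <- match.arg(membership)
  q <- if (membership == "midpoint") peak_midpoints(peaks) else peaks
  sum(GenomicRanges::countOverlaps(q, regions) > 0L)
}

#' Fold enrichment of peaks in a region set
#'
#' Observed fraction of peaks inside the regions (by midpoint, or any >= 1
#' bp overlap) over the fraction expected by chance, which is the base-pair
#' coverage fraction of the regions.
#'
#' @param peaks Non-empty `GRanges` of peaks.
#' @param regions `GRanges` of target regions (merged internally).
#' @param genome Genome; defaults to the peaks' `seqinfo`.
#' @param membership Peak-in-region rule: `"midpoint"` (default) or
#'   `"any_overlap"`.
#' @return A list of class `"enrichment_result"` with `n_obs`, `n_total`,
#'   `f_obs`, `f_exp`, `fold`.
#' @export
fold_enrichment <- function(peaks, regions,
                            genome = GenomeInfoDb::seqinfo(peaks),
                            membership = c("midpoint", "any_overlap")) {
  membership <- match.arg(membership)
  if (length(peaks) == 0L) stop("peaks empty")
  check_same_genome(peaks, regions)
  regions <- merge_intervals(regions)
  f_exp <- coverage_fraction(regions, genome)
  if (f_exp == 0) stop("regions empty")
  n_obs <- count_in_regions(peaks, regions, membership)
  n_total <- length(peaks)
  f_obs <- n_obs / n_total
  structure(list(n_obs = n_obs, n_total = n_total, f_obs = f_obs,
                 f_exp = f_exp, fold = f_obs / f_exp,
                 membership = membership),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Region enrichment (%s membership): %d/%d peaks in regions\n",
              x$membership, x$n_obs, x$n_total))
  cat(sprintf("  f_obs = %.4f, f_exp = %.4f, fold = %.3f\n",
              x$f_obs, x$f_exp, x$fold))
  if (!is.null(x$p_perm))
    cat(sprintf("  p_perm = %.4g (n_perm = %d, seed = %d), p_binom = %.4g\n",
                x$p_perm, x$n_perm, x$seed, x$p_binom))
  invisible(x)
}

# Flatten regions / genome to absolute 0-based coordinates for fast
# membership tests. Returns sorted region starts/ends plus per-chromosome
# offsets.
flatten_regions <- function(regions, genome) {
  L <- as.numeric(GenomeInfoDb::seqlengths(genome))
  off <- c(0, cumsum(L))[seq_along(L)]
  names(off) <- GenomeInfoDb::seqnames(genome)
  regions <- merge_intervals(regions)
  ch <- as.character(GenomicRanges::seqnames(regions))
  s0 <- off[ch] + GenomicRanges::start(regions) - 1
  e0 <- off[ch] + GenomicRanges::end(regions)
  o <- order(s0)
  list(starts = s0[o], ends = e0[o], offsets = off, lengths = L)
}

# Count how many of the peaks [s0, e0) (absolute coords) satisfy the
# membership rule against flattened regions.
flat_count_in <- function(s0, e0, flat, membership) {
  if (membership == "midpoint") {
    mid <- floor((s0 + e0) / 2)
    sum(findInterval(mid, flat$starts) > findInterval(mid, flat$ends))
  } else {
    n_start_lt_end <- findInterval(e0 - 1, flat$starts)
    n_end_le_start <- findInterval(s0, flat$ends)
    sum(n_start_lt_end > n_end_le_start)
  }
}

#' Permutation test for region enrichment
#'
#' Builds a permutation null by redrawing every peak uniformly at random
#' with its length preserved -- on its own chromosome (default) or
#' genome-wide with chromosomes weighted by length -- and compares the
#' observed number of peaks in the regions against the null counts. The
#' permutation p-value uses the add-one rule, `p = (1 + #\{null >=
#' obs\}) / (1 + n_perm)`, so it is never smaller than `1 / (1 + n_perm)`.
#' A binomial upper-tail p-value at the coverage expectation is reported
#' alongside.
#'
#' @inheritParams fold_enrichment
#' @param n_perm Number of permutations (>= 1); default 1000.
#' @param seed Mandatory integer seed.
#' @param placement `"same_chrom"` (default) or `"genome_wide"`.
#' @return An `"enrichment_result"` with `p_perm`, `p_binom`, `n_perm`,
#'   `seed`, `null_counts` added.
#' @export
permutation_test <- function(peaks, regions,
                             genome = GenomeInfoDb::seqinfo(peaks),
                             n_perm = 1000L, seed,
                             placement = c("same_chrom", "genome_wide"),
                             membership = c("midpoint", "any_overlap")) {
  placement <- match.arg(placement)
  membership <- match.arg(membership)
  if (n_perm < 1) stop("n_perm must be >= 1")
  res <- fold_enrichment(peaks, regions, genome, membership)
  flat <- flatten_regions(regions, genome)
  w <- as.numeric(GenomicRanges::width(peaks))
  ch <- as.character(GenomicRanges::seqnames(peaks))
  chlen <- flat$lengths[match(ch, names(flat$offsets))]
  if (placement == "same_chrom" && any(w > chlen))
    stop("peak longer than its chromosome: cannot place under same_chrom")
  n <- length(peaks)
  offs <- flat$offsets[match(ch, names(flat$offsets))]
  valid <- chlen - w + 1
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      if (placement == "same_chrom") {
        s0 <- offs + floor(stats::runif(n) * valid)
      } else {
        idx <- sample.int(length(flat$lengths), n, replace = TRUE,
                          prob = flat$lengths)
        wlen <- flat$lengths[idx]
        ok <- w <= wlen
        if (any(!ok)) { # redraw infeasible chromosomes among feasible ones
          for (i in which(!ok)) {
            feas <- which(flat$lengths >= w[i])
            if (!length(feas)) stop("peak longer than every chromosome")
            idx[i] <- feas[sample.int(length(feas), 1L,
                                      prob = flat$lengths[feas])]
          }
          wlen <- flat$lengths[idx]
        }
        s0 <- flat$offsets[idx] + floor(stats::runif(n) * (wlen - w + 1))
      }
      flat_count_in(s0, s0 + w, flat, membership)
    }, numeric(1))
  })
  res$p_perm <- (1 + sum(null_counts >= res$n_obs)) / (1 + n_perm)
  res$p_binom <- stats::pbinom(res$n_obs - 1L, res$n_total, res$f_exp,
                               lower.tail = FALSE)
  res$n_perm <- as.integer(n_perm)
  res$seed <- as.integer(seed)
  res$null_counts <- null_counts
  res
}

#' Exact test for a 2x2 contingency table
#'
#' Fisher's exact test computed by direct hypergeometric enumeration over
#' the table family with fixed margins. The two-sided p-value uses the
#' point-probability rule: the sum of probabilities of all tables no more
#' probable than the observed one, with a relative tolerance of 1e-7 for
#' ties (the convention of standard exact-test implementations).
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts.
#' @param alternative `"two_sided"` (default), `"greater"` (positive
#'   association, large `tab[1,1]`), or `"less"`.
#' @return The p-value in `(0, 1]`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2)) # 34/70
#' @export
fisher_exact <- function(tab, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.numeric(tab)
  if (length(tab) != 4L || any(tab < 0) || any(tab != floor(tab)))
    stop("tab must be a 2x2 table of non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  a <- tab[1L]; c_ <- tab[2L]; b <- tab[3L]; d <- tab[4L]
  m <- a + b          # row-1 total
  n <- c_ + d         # row-2 total
  k <- a + c_         # column-1 total
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  px <- stats::dhyper(x, m, n, k)
  pa <- px[x == a]
  p <- switch(alternative,
    greater = sum(px[x >= a]),
    less = sum(px[x <= a]),
    two_sided = sum(px[px <= pa * (1 + 1e-7)])
  )
  min(1, p)
}

#' Shuffle peaks to length-matched random positions
#'
#' Draws `n_sets` independent random placements of every peak (length
#' preserved, start uniform over valid positions, same chromosome by
#' default) and pools them. This is the background pool used by
#' [annotate_features()] and [cooccurrence()].
#'
#' @inheritParams permutation_test
#' @param n_sets Number of shuffled copies of the peak set to pool.
#' @return A `GRanges` of `n_sets * length(peaks)` shuffled peaks.
#' @export
shuffle_peaks <- function(peaks, genome = GenomeInfoDb::seqinfo(peaks),
                          n_sets = 1L, seed,
                          placement = c("same_chrom", "genome_wide")) {
  placement <- match.arg(placement)
  L <- as.numeric(GenomeInfoDb::seqlengths(genome))
  nm <- GenomeInfoDb::seqnames(genome)
  w <- rep(as.numeric(GenomicRanges::width(peaks)), n_sets)
  ch <- rep(as.character(GenomicRanges::seqnames(peaks)), n_sets)
  with_seed(seed, {
    if (placement == "genome_wide") {
      idx <- sample.int(length(L), length(w), replace = TRUE, prob = L)
      ch <- nm[idx]
    }
    chlen <- L[match(ch, nm)]
    if (any(w > chlen)) stop("peak longer than its chromosome")
    s0 <- floor(stats::runif(length(w)) * (chlen - w + 1))
    interval_set(ch, s0, s0 + w, genome, sort = FALSE)
  })
}

#' Annotate peaks against feature tracks
#'
#' For each feature track, counts the peaks overlapping it and compares
#' against a pooled background of `n_shuffle` length-matched, same-
#' chromosome shuffles of the peak set. Significance per feature is a
#' Fisher exact test on the 2x2 table `[obs_in, obs_out; shuf_in,
#' shuf_out]`. Tracks named in `point_features` (e.g. TSS/TES supplied as
#' point features) are symmetrically expanded by `tss_flank_bp` before
#' overlap.
#'
#' @param peaks `GRanges` of peaks.
#' @param features Named list of `GRanges` feature tracks on the same
#'   genome.
#' @param genome Genome; defaults to the peaks' `seqinfo`.
#' @param tss_flank_bp Flank in bp applied to `point_features`; default
#'   2000.
#' @param point_features Names of tracks to expand by `tss_flank_bp`.
#' @param n_shuffle Number of shuffled peak-set copies pooled for the
#'   expectation.
#' @param seed Mandatory integer seed.
#' @return A data frame with one row per feature: observed count and
#'   fraction, expected fraction, fold, Fisher p, and BH-adjusted p.
#' @export
annotate_features <- function(peaks, features,
                              genome = GenomeInfoDb::seqinfo(peaks),
                              tss_flank_bp = 2000L,
                              point_features = c("TSS", "TES"),
                              n_shuffle = 10L, seed) {
  if (is.null(names(features)) || any(!nzchar(names(features))))
    stop("features must be a named list")
  shuf <- shuffle_peaks(peaks, genome, n_sets = n_shuffle, seed = seed)
  n_obs_total <- length(peaks)
  n_shuf_total <- length(shuf)
  rows <- lapply(names(features), function(nm) {
    tr <- features[[nm]]
    if (is.null(tr)) {
      warning("feature track '", nm, "' missing; skipped")
      return(NULL)
    }
    if (nm %in% point_features) {
      tr <- GenomicRanges::trim(suppressWarnings(
        GenomicRanges::resize(tr, GenomicRanges::width(tr) + 2L * tss_flank_bp,
                              fix = "center")))
    }
    tr <- merge_intervals(tr)
    obs_in <- unname(overlap_counts(peaks, tr)["n_overlapping"])
    shuf_in <- unname(overlap_counts(shuf, tr)["n_overlapping"])
    f_obs <- obs_in / n_obs_total
    f_exp <- shuf_in / n_shuf_total
    p <- fisher_exact(matrix(c(obs_in, shuf_in,
                               n_obs_total - obs_in,
                               n_shuf_total - shuf_in), 2L))
    data.frame(feature = nm, n_obs = obs_in, n_total = n_obs_total,
               f_obs = f_obs, f_exp = f_exp,
               fold = if (f_exp > 0) f_obs / f_exp else NA_real_,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$fisher_p_bh <- stats::p.adjust(out$fisher_p, "BH")
  out
}

#' Co-occurrence of peaks with a pair of mark tracks
#'
#' Counts the peaks overlapping both marks (>= 1 bp each), estimates the
#' expectation from a pooled set of length-matched, same-chromosome
#' shuffled peaks, and tests the observed-vs-shuffled 2x2 table with the
#' Fisher exact test.
#'
#' @param peaks `GRanges` of peaks.
#' @param markA,markB Non-empty `GRanges` mark tracks on the same genome.
#' @param genome Genome; defaults to the peaks' `seqinfo`.
#' @param n_shuffle Number of shuffled copies pooled for the expectation.
#' @param seed Mandatory integer seed.
#' @return A list with `n_both`, `fraction`, `f_exp`, `fold`, `fisher_p`.
#' @export
cooccurrence <- function(peaks, markA, markB,
                         genome = GenomeInfoDb::seqinfo(peaks),
                         n_shuffle = 10L, seed) {
  if (length(markA) == 0L || length(markB) == 0L) stop("empty mark track")
  check_same_genome(peaks, markA, markB)
  markA <- merge_intervals(markA); markB <- merge_intervals(markB)
  both <- function(x) {
    sum(GenomicRanges::countOverlaps(x, markA) > 0L &
        GenomicRanges::countOverlaps(x, markB) > 0L)
  }
  n_both <- both(peaks)
  shuf <- shuffle_peaks(peaks, genome, n_sets = n_shuffle, seed = seed)
  shuf_both <- both(shuf)
  f_obs <- n_both / length(peaks)
  f_exp <- shuf_both / length(shuf)
  p <- fisher_exact(matrix(c(n_both, shuf_both,
                             length(peaks) - n_both,
                             length(shuf) - shuf_both), 2L))
  list(n_both = n_both, fraction = f_obs, f_exp = f_exp,
       fold = if (f_exp > 0) f_obs / f_exp else NA_real_, fisher_p = p)
}
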