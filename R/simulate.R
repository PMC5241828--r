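# Synthetic-data generators with recoverable ground truth: peak sets with
# a planted subtelomeric enrichment, mark tracks with a planted
# co-occurrence odds ratio, and nucleus images with rim, spots and noise.
# Every generator takes an explicit seed and records it in its truth
# object; identical (parameters, seed) give identical output.

#' Simulate a toy genome
#'
#' Deterministic genome with chromosomes `chr1..chrN` of the given
#' lengths.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of lengths (recycled to `n_chrom`).
#' @param seed Integer seed, recorded for provenance (the construction is
#'   deterministic).
#' @return A `Seqinfo` genome.
#' @export
simulate_genome <- function(n_chrom, lengths, seed = 0L) {
  lengths <- rep_len(as.numeric(lengths), n_chrom)
  make_genome(paste0("chr", seq_len(n_chrom)), lengths)
}

# sample n bases uniformly from an interval set (assumed merged/disjoint,
# which all internal callers guarantee); returns data frame chrom / base0
sample_bases <- function(regions, n) {
  w <- as.numeric(GenomicRanges::width(regions))
  if (sum(w) == 0) stop("cannot sample from an empty region set")
  cw <- cumsum(w)
  u <- floor(stats::runif(n) * cw[length(cw)])
  i <- findInterval(u, c(0, cw[-length(cw)]))
  off <- u - c(0, cw[-length(cw)])[i]
  data.frame(chrom = as.character(GenomicRanges::seqnames(regions))[i],
             base0 = GenomicRanges::start(regions)[i] - 1 + off,
             stringsAsFactors = FALSE)
}

#' Simulate peaks with a planted subtelomeric enrichment
#'
#' Each peak's midpoint falls inside the subtelomeric windows with
#' probability `p = subtel_fold * coverage_fraction(windows)` and
#' uniformly over the complement otherwise, so the planted fold is exactly
#' recoverable in expectation by [fold_enrichment()] with midpoint
#' membership. Peak lengths are geometric with the given mean (or constant
#' in `constant_length` mode), clipped to chromosome bounds.
#'
#' @param genome A `Seqinfo` genome.
#' @param n_peaks Number of peaks (>= 1).
#' @param length_mean Mean peak length in bp.
#' @param subtel_fold Planted fold enrichment (>= 0);
#'   `subtel_fold * coverage_fraction(windows)` must be <= 1.
#' @param window_bp Subtelomeric window width in bp.
#' @param seed Mandatory integer seed.
#' @param constant_length Draw all peaks at exactly `length_mean` bp?
#' @return List with `peaks` (`GRanges`), `windows` (`GRanges`), and
#'   `truth` (planted parameters, per-peak window membership, seed).
#' @export
simulate_peaks <- function(genome, n_peaks, length_mean = 300,
                           subtel_fold = 1, window_bp = 500000L, seed,
                           constant_length = FALSE) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (subtel_fold < 0) stop("subtel_fold must be >= 0")
  windows <- subtelomeric_windows(genome, window_bp)
  cov <- coverage_fraction(windows, genome)
  p <- subtel_fold * cov
  if (p > 1) stop("infeasible fold: subtel_fold * coverage > 1")
  compl <- GenomicRanges::setdiff(genome_ranges(genome), windows)
  if (p < 1 && length(compl) == 0L)
    stop("windows cover the genome; only subtel_fold = 1/coverage feasible")
  with_seed(seed, {
    in_win <- stats::runif(n_peaks) < p
    len <- if (constant_length) rep(length_mean, n_peaks)
           else stats::rgeom(n_peaks, 1 / length_mean) + 1
    mids <- data.frame(chrom = character(n_peaks), base0 = numeric(n_peaks),
                       stringsAsFactors = FALSE)
    if (any(in_win)) mids[in_win, ] <- sample_bases(windows, sum(in_win))
    if (any(!in_win)) mids[!in_win, ] <- sample_bases(compl, sum(!in_win))
    L <- GenomeInfoDb::seqlengths(genome)[mids$chrom]
    s0 <- pmax(0, pmin(mids$base0 - floor(len / 2), L - 1))
    e0 <- pmin(L, s0 + pmax(1, len))
    peaks <- interval_set(mids$chrom, s0, e0, genome,
                          name = paste0("peak", seq_len(n_peaks)))
    list(peaks = peaks, windows = windows,
         truth = list(subtel_fold = subtel_fold, window_bp = window_bp,
                      p_in_window = p, coverage = cov,
                      length_mean = length_mean, n_peaks = n_peaks,
                      in_window = in_win, seed = as.integer(seed)))
  })
}

joint_overlap_probs <- function(pA, pB, odds_ratio) {
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  p11 <- if (odds_ratio == 1) pA * pB else {
    q <- odds_ratio - 1
    disc <- (1 + (pA + pB) * q)^2 - 4 * odds_ratio * q * pA * pB
    if (disc < 0) stop("infeasible marginals/odds ratio")
    (1 + (pA + pB) * q - sqrt(disc)) / (2 * q)
  }
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop("infeasible marginals/odds ratio")
  p11 <- min(max(p11, lo), hi)
  c(p11 = p11, p10 = pA - p11, p01 = pB - p11, p00 = 1 - pA - pB + p11)
}

# starting positions for n intervals of width len fully inside the
# (precomputed, merged) free space
sample_clear_starts <- function(free, len, n, genome) {
  free <- free[GenomicRanges::width(free) >= len + 2]
  if (length(free) == 0L || n == 0L)
    return(interval_set(character(0), numeric(0), numeric(0), genome))
  shr <- GenomicRanges::resize(free, GenomicRanges::width(free) - len + 1,
                               fix = "start")
  b <- sample_bases(shr, n)
  interval_set(b$chrom, b$base0, b$base0 + len, genome, sort = FALSE)
}

#' Simulate a pair of mark tracks with planted co-occurrence
#'
#' For each peak, joint overlap indicators (A, B) are drawn from the 2x2
#' distribution with marginal probability `mark_density` for each mark and
#' the given odds ratio; a mark interval spanning the peak is materialized
#' for each positive indicator. Uniform background intervals (placed clear
#' of all peaks, so indicators stay exact) are added until a length-
#' matched random window overlaps the track with probability about
#' `mark_density` as well -- so length-matched shuffled peaks see the same
#' marginal as the planted peaks, and only the planted odds ratio (not the
#' marginals) separates observed from expected co-occurrence. The track's
#' base coverage is therefore about half of `mark_density` for typical
#' interval lengths.
#'
#' The planted indicators are realized exactly when the peaks are mutually
#' disjoint. Peaks that overlap each other share planted marks, so some
#' negative indicators flip positive; the returned truth records the
#' realized indicators and a warning reports the flips.
#'
#' @param genome A `Seqinfo` genome.
#' @param peaks `GRanges` of peaks.
#' @param odds_ratio Planted odds ratio (> 0).
#' @param mark_density Per-mark marginal overlap probability and target
#'   genome coverage, in (0, 1).
#' @param seed Mandatory integer seed.
#' @return List with `markA`, `markB` (`GRanges`) and `truth` (planted
#'   parameters, per-peak indicators, seed).
#' @export
simulate_mark_tracks <- function(genome, peaks, odds_ratio, mark_density,
                                 seed) {
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  if (mark_density <= 0 || mark_density > 1)
    stop("mark_density must be in (0, 1]")
  pr <- joint_overlap_probs(mark_density, mark_density, odds_ratio)
  n <- length(peaks)
  with_seed(seed, {
    cell <- sample.int(4L, n, replace = TRUE, prob = pr)
    A <- cell %in% c(1L, 2L)
    B <- cell %in% c(1L, 3L)
    mkA <- peaks[A]; mkB <- peaks[B]
    gsize <- genome_size(genome)
    w <- max(20, round(stats::median(GenomicRanges::width(peaks))))
    avoid <- merge_intervals(GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(peaks, GenomicRanges::width(peaks) + 2L,
                            fix = "center"))))
    free <- GenomicRanges::setdiff(genome_ranges(genome), avoid)
    # calibrate the background so a length-matched random window overlaps
    # the finished track with probability ~ mark_density, matching the
    # planted per-peak marginal: a window of width w overlaps a background
    # interval of length w with footprint 2w - 1 bp, and gaps are ~ Poisson
    fill <- function(mk) {
      mkm <- merge_intervals(mk)
      q_pl <- min(1 - 1e-9, sum(as.numeric(
        GenomicRanges::width(mkm) + w - 1)) / gsize)
      ratio <- max((1 - mark_density) / (1 - q_pl), 1e-6)
      n_bg <- min(ceiling(3 * gsize / w),
                  max(0, ceiling(-gsize / (2 * w - 1) * log(ratio))))
      if (n_bg == 0) return(mkm)
      bg <- sample_clear_starts(free, w, n_bg, genome)
      merge_intervals(c(GenomicRanges::granges(mk), bg))
    }
    markA <- fill(mkA); markB <- fill(mkB)
    # realized indicators: exact when peaks are mutually disjoint; peaks
    # overlapping each other share planted marks, which flips indicators
    realA <- GenomicRanges::countOverlaps(peaks, markA) > 0
    realB <- GenomicRanges::countOverlaps(peaks, markB) > 0
    if (!identical(unname(realA), A) || !identical(unname(realB), B))
      warning("overlapping peaks contaminate planted indicators; ",
              sum(realA != A) + sum(realB != B),
              " indicator(s) flipped (use sparser peaks for exact truth)")
    list(markA = markA, markB = markB,
         truth = list(odds_ratio = odds_ratio, mark_density = mark_density,
                      probs = pr, overlap_A = unname(realA),
                      overlap_B = unname(realB), intended_A = A,
                      intended_B = B, seed = as.integer(seed)))
  })
}

ellipse_mask <- function(width, height, cx, cy, a, b, theta = 0) {
  x <- matrix(seq_len(width), width, height)
  y <- matrix(seq_len(height), width, height, byrow = TRUE)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate a multi-nucleus fluorescence image with known ground truth
#'
#' Each nucleus is an ellipse filled with a constant nucleoplasm level
#' plus a peripheral rim `rim_amplitude * exp(-(d - rim_d0)^2 / (2 *
#' rim_sigma^2))`, where `d` is the Euclidean distance to the mask
#' boundary -- so shifting `rim_d0` emulates stains whose peripheral peak
#' sits at different depths. Diffraction-limited spots are planted as
#' Gaussians, either uniformly over the nucleus or at controlled radial
#' area-quantiles of the boundary-distance distribution (quantile q lands
#' in shell `ceiling(q * K)` of a K-shell equal-area partition). Gaussian
#' or Poisson noise is added last.
#'
#' @param width,height Frame size in pixels.
#' @param nuclei List of ellipse specs `list(cx, cy, a, b, theta = 0)`.
#' @param rim_amplitude,rim_sigma,rim_d0 Rim peak height, width (px) and
#'   depth offset from the boundary (px).
#' @param nucleoplasm Constant in-mask intensity level.
#' @param spots `NULL`, or `list(n = spots per nucleus, sigma, amplitude,
#'   radial_quantile = NULL, min_sep = 5 * sigma)`; `radial_quantile` is a
#'   scalar or vector in `[0, 1]` (recycled over the `n` spots), `NULL`
#'   for uniform placement. Spots are planted at least `min_sep` px apart
#'   (best effort), emulating discrete puncta.
#' @param noise `list(type = "none"|"gaussian"|"poisson", sd)`.
#' @param seed Mandatory integer seed.
#' @return List with `image` (matrix), `masks` (integer label matrix), and
#'   `truth` (ellipse specs, planted spot table, parameters, seed).
#' @export
simulate_nucleus_image <- function(width, height, nuclei,
                                   rim_amplitude = 0, rim_sigma = 2,
                                   rim_d0 = 0, nucleoplasm = 100,
                                   spots = NULL,
                                   noise = list(type = "none"), seed) {
  img <- matrix(0, width, height)
  masks <- matrix(0L, width, height)
  spot_tab <- NULL
  with_seed(seed, {
    for (k in seq_along(nuclei)) {
      e <- nuclei[[k]]
      th <- if (is.null(e$theta)) 0 else e$theta
      m <- ellipse_mask(width, height, e$cx, e$cy, e$a, e$b, th)
      if (any(masks[m] > 0)) stop("nuclei must not overlap")
      masks[m] <- k
      img[m] <- img[m] + nucleoplasm
      d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
      if (rim_amplitude > 0)
        img[m] <- img[m] + rim_amplitude *
          exp(-(d[m] - rim_d0)^2 / (2 * rim_sigma^2))
      if (!is.null(spots) && spots$n > 0) {
        idx <- which(m, arr.ind = TRUE)
        din <- d[m]
        q <- spots$radial_quantile
        if (!is.null(q) && (any(q < 0) || any(q > 1)))
          stop("spot radial quantile outside [0, 1]")
        min_sep <- if (is.null(spots$min_sep)) 5 * spots$sigma
                   else spots$min_sep
        ord <- order(din)
        px <- numeric(0); py <- numeric(0)
        for (si in seq_len(spots$n)) {
          for (try in 1:200) {
            if (is.null(q)) {
              pick <- sample.int(nrow(idx), 1L)
              qi <- NA_real_
            } else {
              qi <- q[(si - 1L) %% length(q) + 1L]
              jit <- sample.int(max(1L, round(0.004 * length(ord))), 1L) - 1L
              pos <- min(max(1L, round(qi * length(ord)) + jit), length(ord))
              pick <- ord[pos]
            }
            cx <- idx[pick, 1]; cy <- idx[pick, 2]
            if (!length(px) ||
                min((px - cx)^2 + (py - cy)^2) >= min_sep^2) break
          }
          px <- c(px, cx); py <- c(py, cy)
          sx <- cx; sy <- cy
          r <- ceiling(4 * spots$sigma)
          xr <- max(1, sx - r):min(width, sx + r)
          yr <- max(1, sy - r):min(height, sy + r)
          g <- outer((xr - sx)^2, (yr - sy)^2, "+")
          img[xr, yr] <- img[xr, yr] +
            spots$amplitude * exp(-g / (2 * spots$sigma^2))
          spot_tab <- rbind(spot_tab,
            data.frame(x = sx, y = sy, sigma = spots$sigma,
                       amplitude = spots$amplitude, nucleus = k,
                       radial_quantile = qi, provenance = "planted"))
        }
      }
    }
    if (identical(noise$type, "gaussian")) {
      img <- pmax(img + stats::rnorm(length(img), 0, noise$sd), 0)
    } else if (identical(noise$type, "poisson")) {
      img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                    width, height)
    }
    list(image = img, masks = masks,
         truth = list(nuclei = nuclei, spots = spot_tab,
                      rim_amplitude = rim_amplitude, rim_sigma = rim_sigma,
                      rim_d0 = rim_d0, nucleoplasm = nucleoplasm,
                      noise = noise, seed = as.integer(seed)))
  })
}
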