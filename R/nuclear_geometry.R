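# Nucleus segmentation and equal-area erosion-shell partitioning.
#
# Image convention throughout the package: a 2-D image is a base matrix
# indexed [x, y] (EBImage's convention), so a point (x, y) in pixel
# coordinates maps to image[round(x), round(y)].

#' Segment nuclei from a DNA-counterstain image
#'
#' Global Otsu threshold, optional hole filling, connected components
#' (8-connected), removal of regions below `min_area_px`, and relabelling
#' with labels sorted by descending area.
#'
#' @param image Numeric matrix of finite intensities.
#' @param min_area_px Minimum region area kept, in pixels.
#' @param fill_holes Fill holes in the binary mask before labelling?
#' @return Integer label matrix (0 = background, k = nucleus k).
#' @export
segment_nuclei <- function(image, min_area_px = 100L, fill_holes = TRUE) {
  if (!all(is.finite(image))) stop("image must be finite-valued")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("blank image (zero variance): no nuclei found")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  bin <- EBImage::Image(norm > th)
  if (fill_holes) bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) {
    warning("no region of at least ", min_area_px, " px")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Partition a nucleus mask into concentric equal-area shells
#'
#' The radial-positioning ("erosion script") partition: the Euclidean
#' distance transform from background is computed over the mask and in-mask
#' pixels are binned by area quantiles of the distance values into
#' `n_shells` shells of equal area. Shell 1 is the outermost (smallest
#' distances), shell `n_shells` the innermost. Quantile ties are broken
#' outward: all pixels of a tied distance class go to the lower shell
#' index, so shell areas deviate from `total / n_shells` by at most one tie
#' class. An `"equal_width"` mode bins by fixed distance bands instead
#' (the repeated fixed-width erosion alternative).
#'
#' @param mask Binary (or 0/1 integer) matrix; a single non-empty nucleus.
#' @param n_shells Number of shells; default 5.
#' @param method `"equal_area"` (default) or `"equal_width"`.
#' @return An object of class `"shell_partition"`: list with `labels`
#'   (integer matrix, 0 outside the mask), `n_shells`, `areas` (pixels per
#'   shell), `method`.
#' @export
shell_partition <- function(mask, n_shells = 5L,
                            method = c("equal_area", "equal_width")) {
  method <- match.arg(method)
  m <- mask > 0
  n_in <- sum(m)
  if (n_in == 0L) stop("empty mask")
  if (n_in < n_shells) stop("mask smaller than n_shells pixels")
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (n_shells == 1L) {
    labels[m] <- 1L
  } else {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
    din <- d[m]
    if (method == "equal_area") {
      breaks <- stats::quantile(din, seq_len(n_shells - 1L) / n_shells,
                                type = 1, names = FALSE)
    } else {
      breaks <- max(din) * seq_len(n_shells - 1L) / n_shells
    }
    sh <- rep(1L, n_in)
    for (b in breaks) sh <- sh + (din > b)
    labels[m] <- sh
  }
  structure(list(labels = labels, n_shells = as.integer(n_shells),
                 areas = tabulate(labels[labels > 0L], n_shells),
                 method = method),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat(sprintf("Shell partition (%s): %d shells over %d px\n",
              x$method, x$n_shells, sum(x$areas)))
  cat("  areas:", paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

#' Assign points to shells of a partition
#'
#' Each point is mapped to the shell of its containing pixel (nearest-pixel
#' rounding). Points outside the mask (or the image) are counted
#' separately, not dropped silently.
#'
#' @param points Two-column matrix or data frame of (x, y) pixel
#'   coordinates.
#' @param partition A `"shell_partition"`.
#' @return List with `shell` (integer per point, `NA` when outside),
#'   `counts` (length `n_shells`), `n_outside`.
#' @export
assign_to_shells <- function(points, partition) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  i <- round(pts[, 1]); j <- round(pts[, 2])
  lab <- partition$labels
  ok <- i >= 1 & i <= nrow(lab) & j >= 1 & j <= ncol(lab)
  shell <- rep(NA_integer_, nrow(pts))
  shell[ok] <- lab[cbind(i[ok], j[ok])]
  shell[!is.na(shell) & shell == 0L] <- NA_integer_
  list(shell = shell,
       counts = tabulate(shell[!is.na(shell)], partition$n_shells),
       n_outside = sum(is.na(shell)))
}

#' Compare two shell count distributions
#'
#' Per shell, a Fisher exact test of shell-s membership between the two
#' conditions (table `[[a_s, A - a_s], [b_s, B - b_s]]`); overall, a
#' chi-square test on the shells x conditions contingency table.
#'
#' @param counts_a,counts_b Non-negative integer count vectors of equal
#'   length (one entry per shell).
#' @return List with `fisher_p` (per shell), `chisq_p` (overall).
#' @export
shell_distribution_test <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length")
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  A <- sum(counts_a); B <- sum(counts_b)
  if (A == 0 && B == 0) stop("both totals zero")
  fp <- vapply(seq_along(counts_a), function(s) {
    fisher_exact(matrix(c(counts_a[s], counts_b[s],
                          A - counts_a[s], B - counts_b[s]), 2L))
  }, numeric(1))
  tab <- rbind(counts_a, counts_b)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]   # zero-margin shells carry
  chisq_p <- if (ncol(tab) < 2L) NA_real_ else   # no information
    unname(suppressWarnings(stats::chisq.test(tab))$p.value)
  list(fisher_p = fp, chisq_p = chisq_p)
}
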