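# Intensity quantification: line profiles across the nucleus, the
# peripheral-enrichment ratio, background-subtracted nuclear means, the
# three-circle spot-enrichment ratio, and particle densities.

bilinear <- function(image, x, y) {
  # sample image[x, y] at real-valued coordinates; clamps to the frame
  x <- pmin(pmax(x, 1), nrow(image))
  y <- pmin(pmax(y, 1), ncol(image))
  x0 <- pmin(floor(x), nrow(image) - 1L); x1 <- x0 + 1L
  y0 <- pmin(floor(y), ncol(image) - 1L); y1 <- y0 + 1L
  fx <- x - x0; fy <- y - y0
  image[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    image[cbind(x1, y0)] * fx * (1 - fy) +
    image[cbind(x0, y1)] * (1 - fx) * fy +
    image[cbind(x1, y1)] * fx * fy
}

mask_moments <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cen <- sweep(idx, 2, ctr)
  list(centroid = ctr, cov = crossprod(cen) / nrow(idx), n = nrow(idx))
}

#' Intensity profile along a chord through a nucleus
#'
#' Samples the image at unit-pixel steps by bilinear interpolation along a
#' straight chord through the mask centroid -- the mask's major axis by
#' default, its minor axis, or an arbitrary segment given by endpoints.
#' The chord is clipped to the mask's extent along the chosen direction
#' plus a 2-pixel margin; `background` is subtracted and negative values
#' are clamped to zero.
#'
#' Each sample averages a short band of `band_px` pixels perpendicular to
#' the chord (the "line width" of interactive profile tools), restricted
#' to in-mask band positions when the sample point itself is in the mask;
#' this suppresses pixel noise, which otherwise biases the edge-maximum
#' statistic upward. Set `band_px = 1` for a single-pixel line.
#'
#' @param image Numeric matrix (convention `[x, y]`).
#' @param mask Binary matrix, one nucleus; area must be >= 16 px.
#' @param axis `"major"` (default), `"minor"`, or `"segment"`.
#' @param background Scalar background level subtracted from all samples.
#' @param band_px Width of the perpendicular averaging band in pixels
#'   (odd; default 7).
#' @param endpoints For `axis = "segment"`: 2x2 matrix of (x, y) endpoints.
#' @return An object of class `"line_profile"`: data frame with `position`
#'   (pixels along the chord), `intensity`, `in_mask`.
#' @export
line_profile <- function(image, mask, axis = c("major", "minor", "segment"),
                         background = 0, band_px = 7L, endpoints = NULL) {
  axis <- match.arg(axis)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  mm <- mask_moments(mask)
  if (mm$n < 16L) stop("degenerate mask (area < 16 px)")
  if (axis == "segment") {
    if (is.null(endpoints)) stop("axis = 'segment' requires endpoints")
    p0 <- as.numeric(endpoints[1, ]); p1 <- as.numeric(endpoints[2, ])
    u <- p1 - p0; len <- sqrt(sum(u^2)); u <- u / len
    t <- seq(0, len, by = 1)
    pos <- cbind(p0[1] + t * u[1], p0[2] + t * u[2])
  } else {
    eg <- eigen(mm$cov, symmetric = TRUE)
    u <- eg$vectors[, if (axis == "major") 1L else 2L]
    idx <- which(mask > 0, arr.ind = TRUE)
    proj <- (idx[, 1] - mm$centroid[1]) * u[1] +
            (idx[, 2] - mm$centroid[2]) * u[2]
    t <- seq(floor(min(proj)) - 2, ceiling(max(proj)) + 2, by = 1)
    pos <- cbind(mm$centroid[1] + t * u[1], mm$centroid[2] + t * u[2])
  }
  xi <- round(pos[, 1]); yi <- round(pos[, 2])
  inb <- xi >= 1 & xi <= nrow(mask) & yi >= 1 & yi <= ncol(mask)
  inm <- inb
  inm[inb] <- mask[cbind(xi[inb], yi[inb])] > 0
  perp <- c(-u[2], u[1])
  offs <- seq_len(band_px) - (band_px + 1) / 2
  acc <- matrix(0, nrow(pos), length(offs))
  use <- matrix(TRUE, nrow(pos), length(offs))
  for (k in seq_along(offs)) {
    bx <- pos[, 1] + offs[k] * perp[1]
    by <- pos[, 2] + offs[k] * perp[2]
    acc[, k] <- bilinear(image, bx, by)
    bi <- round(bx); bj <- round(by)
    okb <- bi >= 1 & bi <= nrow(mask) & bj >= 1 & bj <= ncol(mask)
    bin <- okb
    bin[okb] <- mask[cbind(bi[okb], bj[okb])] > 0
    # where the centre sample is in-mask, drop band points that fall out
    use[, k] <- !inm | bin
  }
  vals <- rowSums(acc * use) / pmax(rowSums(use), 1)
  vals <- pmax(vals - background, 0)
  structure(data.frame(position = t - t[1], intensity = vals, in_mask = inm),
            class = c("line_profile", "data.frame"))
}

#' Peripheral-enrichment ratio of a line profile
#'
#' The rim-enrichment statistic: the profile's two edge maxima (Max1 over
#' the first `edge_fraction` of in-mask samples, Max2 over the last) are
#' averaged and divided by the median of the plateau, the central 50% of
#' in-mask samples. A flat profile gives exactly 1; a nucleus with a bright
#' rim at both mask edges gives the rim/plateau intensity ratio.
#'
#' Intensities must be background-corrected first: the ratio is invariant
#' under multiplicative rescaling but not under additive offsets.
#'
#' @param profile A `"line_profile"` (or data frame with `intensity` and
#'   `in_mask` columns).
#' @param edge_fraction Fraction of in-mask samples in each edge window;
#'   default 0.25.
#' @param plateau_fraction Central fraction of in-mask samples forming the
#'   plateau; default 0.5.
#' @return An object of class `"peripheral_enrichment"`: list with `max1`,
#'   `max2`, `plateau_median`, `ratio`.
#' @export
peripheral_enrichment <- function(profile, edge_fraction = 0.25,
                                  plateau_fraction = 0.5) {
  v <- profile$intensity[profile$in_mask]
  n <- length(v)
  if (n < 8L) stop("need at least 8 in-mask samples")
  k <- max(1L, floor(edge_fraction * n))
  max1 <- max(v[seq_len(k)])
  max2 <- max(v[seq.int(n - k + 1L, n)])
  half <- (1 - plateau_fraction) / 2
  i1 <- floor(n * half) + 1L
  i2 <- ceiling(n * (1 - half))
  med <- stats::median(v[i1:i2])
  if (med <= 0) stop("flat/empty plateau (median <= 0)")
  structure(list(max1 = max1, max2 = max2, plateau_median = med,
                 ratio = 0.5 * (max1 + max2) / med),
            class = "peripheral_enrichment")
}

#' @export
print.peripheral_enrichment <- function(x, ...) {
  cat(sprintf("Peripheral enrichment: (%.3g + %.3g)/2 / %.3g = %.3f\n",
              x$max1, x$max2, x$plateau_median, x$ratio))
  invisible(x)
}

#' Background-subtracted mean nuclear intensity
#'
#' Per nucleus, the mean of in-mask intensities minus the background
#' (median of out-of-mask pixels by default, or a supplied constant),
#' clamped at zero.
#'
#' @param image Numeric matrix.
#' @param mask Integer label matrix (0 = background).
#' @param background `"median_outside"` (default) or `"constant"`.
#' @param bg_value Background level when `background = "constant"`.
#' @return Named numeric vector, one value per nucleus label.
#' @export
nuclear_mean_intensity <- function(image, mask,
                                   background = c("median_outside", "constant"),
                                   bg_value = 0) {
  background <- match.arg(background)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  bg <- if (background == "median_outside") {
    if (!any(mask == 0)) stop("no out-of-mask pixels for background")
    stats::median(image[mask == 0])
  } else bg_value
  labs <- sort(unique(mask[mask > 0]))
  out <- vapply(labs, function(k) max(0, mean(image[mask == k]) - bg),
                numeric(1))
  names(out) <- labs
  out
}

circle_mean <- function(image, center, radius_px) {
  cx <- center[1]; cy <- center[2]
  xr <- max(1, floor(cx - radius_px)):min(nrow(image), ceiling(cx + radius_px))
  yr <- max(1, floor(cy - radius_px)):min(ncol(image), ceiling(cy + radius_px))
  g <- expand.grid(x = xr, y = yr)
  sel <- (g$x - cx)^2 + (g$y - cy)^2 <= radius_px^2
  if (!any(sel)) stop("empty circle")
  mean(image[cbind(g$x[sel], g$y[sel])])
}

#' Three-circle spot-enrichment ratio
#'
#' The tethered-locus (LacO/LacI) enrichment measure: mean intensities are
#' taken in three equal circles -- around the spot, at a nuclear reference
#' position, and outside the cell. The outside circle is the background,
#' subtracted from both others, and the ratio is
#' `(spot - outside) / (nuclear - outside)`.
#'
#' @param image Numeric matrix.
#' @param spot_center,nuclear_ref_center,outside_center (x, y) circle
#'   centres; the circles must be pairwise disjoint.
#' @param radius_px Circle radius in pixels; default 3.
#' @return The enrichment ratio (1 = no enrichment over nucleoplasm).
#' @examples
#' img <- matrix(50, 40, 40)
#' img[5:11, 5:11] <- 150; img[5:11, 25:31] <- 300
#' spot_enrichment(img, c(8, 28), c(8, 8), c(30, 30))
#' @export
spot_enrichment <- function(image, spot_center, nuclear_ref_center,
                            outside_center, radius_px = 3L) {
  ctrs <- rbind(spot_center, nuclear_ref_center, outside_center)
  dd <- stats::dist(ctrs)
  if (any(dd <= 2 * radius_px))
    stop("the three circles must be disjoint")
  ms <- circle_mean(image, spot_center, radius_px)
  mn <- circle_mean(image, nuclear_ref_center, radius_px)
  mo <- circle_mean(image, outside_center, radius_px)
  if (mn <= mo) stop("non-positive nuclear signal")
  (ms - mo) / (mn - mo)
}

#' Point density per compartment
#'
#' Counts points inside each (disjoint) compartment mask and divides by
#' the compartment area in square micrometres -- e.g. immuno-gold particle
#' densities per nuclear sub-compartment.
#'
#' @param points Two-column matrix/data frame of (x, y) pixel coordinates.
#' @param compartment_masks Named list of binary matrices; must be
#'   pairwise disjoint.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @return Named numeric vector of densities (count per um^2).
#' @export
particle_density <- function(points, compartment_masks, pixel_size_um) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (is.null(names(compartment_masks)))
    stop("compartment_masks must be named")
  acc <- NULL
  for (m in compartment_masks) {
    mm <- m > 0
    if (is.null(acc)) acc <- mm * 1L else {
      if (any(acc + mm > 1)) stop("compartment masks must be disjoint")
      acc <- acc + mm
    }
  }
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  vapply(compartment_masks, function(m) {
    area_px <- sum(m > 0)
    if (area_px == 0) stop("zero-area compartment")
    i <- round(pts[, 1]); j <- round(pts[, 2])
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    n <- sum(m[cbind(i[ok], j[ok])] > 0)
    n / (area_px * pixel_size_um^2)
  }, numeric(1))
}
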