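test_that("line profiles sample constant images exactly and subtract background", {
  ell <- ellipse_image(120, 90, a = 50, b = 35)
  img <- matrix(7, 120, 90)
  prof <- line_profile(img, ell$mask)
  expect_true(all(prof$intensity[prof$in_mask] == 7))
  prof2 <- line_profile(img, ell$mask, background = 5)
  expect_true(all(prof2$intensity[prof2$in_mask] == 2))
  prof3 <- line_profile(img, ell$mask, background = 10)
  expect_true(all(prof3$intensity == 0))  # clamped at zero
  expect_equal(diff(prof$position), rep(1, nrow(prof) - 1))
  tiny <- matrix(FALSE, 20, 20); tiny[10, 8:12] <- TRUE
  expect_error(line_profile(img[1:20, 1:20], tiny), "degenerate")
})

test_that("line profiles have rim maxima near the mask edges on rim images", {
  sim <- simulate_nucleus_image(
    200, 150, nuclei = list(list(cx = 100, cy = 75, a = 70, b = 45)),
    rim_amplitude = 200, rim_sigma = 2, rim_d0 = 3, nucleoplasm = 100,
    seed = 4)
  prof <- line_profile(sim$image, sim$masks == 1)
  v <- prof$intensity[prof$in_mask]
  n <- length(v)
  expect_gt(max(v[1:round(n / 4)]), 250)           # rim present at both edges
  expect_gt(max(v[(n - round(n / 4)):n]), 250)
  expect_lt(stats::median(v[round(n / 4):round(3 * n / 4)]), 130)
})

test_that("peripheral enrichment reproduces forced and planted ratios", {
  flat <- data.frame(position = 0:19, intensity = rep(5, 20),
                     in_mask = TRUE)
  expect_equal(peripheral_enrichment(flat)$ratio, 1.0)

  v <- rep(1, 20); v[3] <- 4; v[18] <- 4
  hand <- data.frame(position = 0:19, intensity = v, in_mask = TRUE)
  pe <- peripheral_enrichment(hand)
  expect_equal(pe$max1, 4); expect_equal(pe$max2, 4)
  expect_equal(pe$plateau_median, 1)
  expect_equal(pe$ratio, 4.0)

  expect_error(peripheral_enrichment(flat[1:5, ]), "at least 8")
  zero <- data.frame(position = 0:19, intensity = 0, in_mask = TRUE)
  expect_error(peripheral_enrichment(zero), "plateau")

  # planted rim/plateau ratio recovered across orientations, noise-free
  for (theta in c(0, 0.5, 1.1)) {
    for (R in c(1.5, 3)) {
      A <- 100 * (R - 1)
      sim <- simulate_nucleus_image(
        200, 160, nuclei = list(list(cx = 100, cy = 80, a = 70, b = 48,
                                     theta = theta)),
        rim_amplitude = A, rim_sigma = 2, rim_d0 = 3, nucleoplasm = 100,
        seed = 5)
      pe <- peripheral_enrichment(line_profile(sim$image, sim$masks == 1))
      expect_lt(abs(pe$ratio / R - 1), 0.05)
    }
  }
})

test_that("the ratio is scale-invariant but not offset-invariant", {
  sim <- simulate_nucleus_image(
    200, 150, nuclei = list(list(cx = 100, cy = 75, a = 70, b = 45)),
    rim_amplitude = 200, rim_sigma = 2, rim_d0 = 3, nucleoplasm = 100,
    seed = 6)
  base <- peripheral_enrichment(line_profile(sim$image, sim$masks == 1))$ratio
  scaled <- peripheral_enrichment(
    line_profile(sim$image * 3.7, sim$masks == 1))$ratio
  expect_equal(scaled, base, tolerance = 1e-10)
  offset <- peripheral_enrichment(
    line_profile(sim$image + 500, sim$masks == 1))$ratio
  expect_lt(offset, base)  # additive offset dilutes the ratio
  # subtracting the offset as background restores it
  restored <- peripheral_enrichment(
    line_profile(sim$image + 500, sim$masks == 1, background = 500))$ratio
  expect_equal(restored, base, tolerance = 1e-10)
})

test_that("rim-free nuclei give ratio ~1 under noise", {
  run <- function(sd) vapply(1:40, function(s) {
    sim <- simulate_nucleus_image(
      160, 120, nuclei = list(list(cx = 80, cy = 60, a = 60, b = 40)),
      nucleoplasm = 200, noise = list(type = "gaussian", sd = sd),
      seed = s)
    peripheral_enrichment(line_profile(sim$image, sim$masks == 1))$ratio
  }, numeric(1))
  r10 <- run(10)
  expect_lt(abs(mean(r10) - 1), 0.05)
  r20 <- run(20)   # the edge maximum is noise-biased upward, never below 1
  expect_lt(abs(mean(r20) - 1), 0.1)
  expect_true(all(r20 >= 1))
})

test_that("nuclear mean intensities subtract background per nucleus", {
  mask <- matrix(0L, 60, 40); mask[10:25, 10:30] <- 1L; mask[40:55, 10:30] <- 2L
  img <- matrix(4, 60, 40)
  img[mask == 1] <- 10; img[mask == 2] <- 8
  out <- nuclear_mean_intensity(img, mask)
  expect_equal(unname(out), c(6, 4))
  out2 <- nuclear_mean_intensity(img, mask, background = "constant",
                                 bg_value = 0)
  expect_equal(unname(out2), c(10, 8))
  # planted means recovered under noise
  set.seed(3)
  noisy <- img + rnorm(length(img), 0, 2)
  out3 <- nuclear_mean_intensity(matrix(noisy, 60, 40), mask)
  expect_true(all(abs(out3 - c(6, 4)) < 1))
})

test_that("three-circle spot enrichment reproduces the ratio formula", {
  img <- matrix(50, 60, 60)
  img[8:14, 8:14] <- 150    # nuclear reference region
  img[8:14, 40:46] <- 300   # spot region
  r <- spot_enrichment(img, spot_center = c(11, 43),
                       nuclear_ref_center = c(11, 11),
                       outside_center = c(45, 25), radius_px = 3)
  expect_equal(r, 2.5)
  img2 <- matrix(50, 60, 60); img2[8:14, 8:14] <- 150; img2[8:14, 40:46] <- 150
  expect_equal(spot_enrichment(img2, c(11, 43), c(11, 11), c(45, 25)), 1.0)
  expect_error(spot_enrichment(img, c(11, 43), c(12, 43), c(45, 25)),
               "disjoint")
  flat <- matrix(50, 60, 60)
  expect_error(spot_enrichment(flat, c(11, 43), c(11, 11), c(45, 25)),
               "non-positive")
})

test_that("a planted 4x tethered spot is recovered within 10% under noise", {
  ratios <- vapply(1:10, function(s) {
    sim <- simulate_nucleus_image(
      200, 150, nuclei = list(list(cx = 100, cy = 75, a = 70, b = 45)),
      nucleoplasm = 100,
      spots = list(n = 1, sigma = 3, amplitude = 300,
                   radial_quantile = 0.9),
      noise = list(type = "gaussian", sd = 5), seed = s)
    sp <- sim$truth$spots
    spot_enrichment(sim$image, c(sp$x, sp$y),
                    nuclear_ref_center = c(60, 75),
                    outside_center = c(15, 15), radius_px = 2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 4 - 1), 0.1)
})

test_that("particle densities are counts per square micrometre", {
  nuc <- matrix(FALSE, 40, 40); nuc[5:24, 5:24] <- TRUE   # 400 px
  cyt <- matrix(FALSE, 40, 40); cyt[30:39, 30:39] <- TRUE # 100 px
  # pixel size 0.0707 um -> nuc area = 400 * 0.005 = 2 um^2
  px <- sqrt(0.005)
  pts <- cbind(runif(10, 5, 24), runif(10, 5, 24))
  d <- particle_density(round(pts), list(nucleus = nuc, cytoplasm = cyt), px)
  expect_equal(unname(d["nucleus"]), 5.0)
  expect_equal(unname(d["cytoplasm"]), 0.0)
  overlap <- matrix(FALSE, 40, 40); overlap[20:29, 20:29] <- TRUE
  expect_error(particle_density(pts, list(a = nuc, b = overlap), px),
               "disjoint")
  empty <- matrix(FALSE, 40, 40)
  expect_error(particle_density(pts, list(a = nuc, b = empty), px),
               "zero-area")
})

test_that("a planted Poisson point process recovers its rate", {
  mask <- matrix(TRUE, 100, 100)
  px <- 0.1                        # 100x100 px = 100 um^2
  lambda <- 3
  set.seed(17)
  dens <- vapply(1:50, function(i) {
    n <- rpois(1, lambda * 100)
    pts <- cbind(runif(n, 1, 100), runif(n, 1, 100))
    particle_density(pts, list(all = mask), px)[["all"]]
  }, numeric(1))
  expect_lt(abs(mean(dens) / lambda - 1), 0.1)
})
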