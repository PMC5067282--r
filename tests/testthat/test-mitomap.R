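test_that("segmentation thresholds behave on two-level and noisy images", {
  img <- matrix(0, 40, 40); img[10:20, 5:30] <- 100
  expect_identical(segment_image(img, "otsu"), img == 100)
  expect_false(any(segment_image(img, "fixed", threshold = 150)))
  expect_error(segment_image(matrix(7, 5, 5), "otsu"), "fixed")
  expect_error(segment_image(img, "fixed"), "threshold")

  # balanced noisy two-class image: misclassification < 1%
  set.seed(31)
  truth <- matrix(FALSE, 100, 100); truth[, 1:50] <- TRUE
  noisy <- 100 * truth + matrix(rnorm(1e4, 0, 12), 100)
  expect_lt(mean(segment_image(noisy, "otsu") != truth), 0.01)
})

test_that("mito_sholl bins foreground pixels into half-open pixel shells", {
  mask <- matrix(FALSE, 20, 20)
  mask[10, 17] <- TRUE      # distance from (10, 10): 7 -> shell [7, 8)
  prof <- mito_sholl(mask, c(10, 10))
  expect_equal(sum(prof$counts), 1)
  expect_equal(prof$counts[8], 1)

  mask[3, 3] <- TRUE        # distance sqrt(98) = 9.899 -> shell [9, 10)
  prof <- mito_sholl(mask, c(10, 10))
  expect_equal(prof$counts[10], 1)
  expect_equal(sum(prof$counts), 2)

  empty <- mito_sholl(matrix(FALSE, 5, 5), c(3, 3))
  expect_equal(sum(empty$counts), 0)
  expect_error(mito_sholl(mask, c(100, 2)), "outside")
})

test_that("mito_sholl equals brute-force per-pixel binning on random masks", {
  set.seed(77)
  for (rep in 1:8) {
    mask <- matrix(runif(30 * 35) < 0.12, 30, 35)
    center <- c(runif(1, 1, 35), runif(1, 1, 30))
    prof <- mito_sholl(mask, center)
    expect_equal(prof$counts, brute_pixel_shells(mask, center),
                 info = paste("rep", rep))
    expect_equal(sum(prof$counts), sum(mask))
  }
})

test_that("mpm produces a valid normalized cumulative curve", {
  # all mass innermost -> flat 1
  prof <- radial_profile(0:5, c(10, 0, 0, 0, 0), "pixels")
  cdf <- mpm(prof, 5)
  expect_equal(cdf$cumulative_fraction, rep(1, 5))

  # uniform counts -> straight line to 1
  u <- mpm(radial_profile(0:10, rep(3, 10), "pixels"), 10)
  expect_equal(u$cumulative_fraction, seq(0.1, 1, by = 0.1))
  expect_equal(u$normalized_distance, seq(0.1, 1, by = 0.1))

  # arbitrary profile: non-decreasing, ends at 1
  set.seed(5)
  p <- radial_profile(0:30, rpois(30, 4), "pixels")
  c2 <- mpm(p, 40)
  expect_true(all(diff(c2$cumulative_fraction) >= 0))
  expect_equal(max(c2$cumulative_fraction), 1)

  expect_error(mpm(radial_profile(0:3, c(0, 0, 0), "pixels"), 3), "zero total")
  expect_error(mpm(prof, 0.5), "max_extent")
})

test_that("mito60 inverts the cumulative curve with interpolation", {
  # uniform density: CDF is the identity -> exactly 0.6
  u <- mpm(radial_profile(seq(0, 100, by = 10), rep(5, 10), "pixels"), 100)
  expect_equal(mito60(u), 0.6, tolerance = 1e-12)

  # step CDF with all mass in the shell [0.6, 0.7): the curve jumps 0 -> 1
  # across that shell, so the interpolated 60% point is 0.6 + 0.6 * 0.1
  s <- mpm(radial_profile(0:10, c(rep(0, 6), 20, 0, 0, 0), "pixels"), 10)
  expect_equal(mito60(s), 0.66)

  # analytic truncated-exponential inversion, tau = 0.3
  tau <- 0.3; n <- 2000
  set.seed(42)
  u01 <- runif(n)
  x <- -tau * log(1 - u01 * (1 - exp(-1 / tau)))    # inverse-CDF sampling
  est <- pipeline_mito60(mitochondrion_set(x * 300, 1), 300)
  expect_lt(abs(est - analytic_mito60(0.3)), 0.02)

  # proximally shifted density has strictly smaller Mito60 than uniform
  unif <- pipeline_mito60(mitochondrion_set(u01 * 300, 1), 300)
  expect_lt(est, unif)
})

test_that("mitochondrial_index is the mito/dendrite area ratio in the ROI", {
  dend <- matrix(FALSE, 30, 30); dend[5:25, 5:25] <- TRUE
  expect_equal(mitochondrial_index(dend, dend), 1.0)
  expect_equal(mitochondrial_index(matrix(FALSE, 30, 30), dend), 0.0)

  mito <- matrix(FALSE, 30, 30); mito[5:10, 5:25] <- TRUE   # 6 x 21 painted
  expect_equal(mitochondrial_index(mito, dend), (6 * 21) / (21 * 21))

  # mito signal outside the dendrite mask does not count
  mito2 <- mito; mito2[28:30, 28:30] <- TRUE
  expect_equal(mitochondrial_index(mito2, dend),
               mitochondrial_index(mito, dend))

  roi <- matrix(FALSE, 30, 30); roi[1:4, 1:4] <- TRUE
  expect_error(mitochondrial_index(mito, dend, roi), "no dendrite area")
  expect_error(mitochondrial_index(mito, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("occupancy_gaps measures unoccupied dendritic length", {
  # one 10-um mitochondrion centered on a 40-um path -> 75% unoccupied
  g <- occupancy_gaps(40, mitochondrion_set(20, 10), step = 0.1)
  expect_equal(g$fraction_unoccupied, 0.75)
  expect_equal(nrow(g$gap_segments), 2)
  expect_equal(g$gap_segments$start, c(0, 25))
  expect_equal(g$gap_segments$end, c(15, 40))

  # tiling mitochondria -> fully occupied
  tiling <- mitochondrion_set(seq(2.5, 37.5, by = 5), 5)
  expect_equal(occupancy_gaps(40, tiling)$fraction_unoccupied, 0)

  # empty set -> one full-length gap
  e <- occupancy_gaps(40, mitochondrion_set(numeric(0), numeric(0)))
  expect_equal(e$fraction_unoccupied, 1)
  expect_equal(e$gap_segments, data.frame(start = 0, end = 40))
})

test_that("occupancy fraction matches interval-union arithmetic and is
           monotone in the number of mitochondria", {
  set.seed(19)
  L <- 60; step <- 0.1
  pos <- runif(25, 0, L); len <- runif(25, 1, 4)
  # independent oracle: merge footprints, count occupied sample midpoints
  n_cells <- round(L / step)
  iv <- cbind(pmax(0, pos - len / 2), pmin(L, pos + len / 2))
  iv <- iv[order(iv[, 1]), ]
  merged <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
    else merged <- rbind(merged, iv[i, ])
  }
  occ <- 0
  for (i in seq_len(nrow(merged))) {
    ks <- which((seq_len(n_cells) - 0.5) * step >= merged[i, 1] &
                (seq_len(n_cells) - 0.5) * step <= merged[i, 2])
    occ <- occ + length(ks)
  }
  expect_equal(
    occupancy_gaps(L, mitochondrion_set(pos, len), step = step)$fraction_unoccupied,
    1 - occ / n_cells)

  # adding mitochondria never increases the unoccupied fraction
  fr <- vapply(seq(5, 25, by = 5), function(k)
    occupancy_gaps(L, mitochondrion_set(pos[1:k], len[1:k]),
                   step = step)$fraction_unoccupied, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("axonal density and relative positions are simple ratios", {
  m12 <- mitochondrion_set(seq(2, 50, length.out = 12), 1)
  expect_equal(axonal_density(52, m12), 12 * 10 / 52)
  expect_equal(axonal_density(52, mitochondrion_set(numeric(0), numeric(0))), 0)
  expect_equal(axonal_density(104, mitochondrion_set(rep(1, 24), 1)),
               axonal_density(52, m12))     # homogeneity

  expect_equal(relative_positions(100, mitochondrion_set(c(25, 100), 1)),
               c(0.25, 1.0))
  # uniform placements approach the uniform law (KS distance at n = 5000)
  ms <- place_mitochondria(500, placement_model("uniform",
                                                n_mitochondria = 5000),
                           seed = 8)
  rel <- relative_positions(500, ms)
  D <- suppressWarnings(ks.test(rel, "punif")$statistic)
  expect_lt(D, 0.03)
})
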