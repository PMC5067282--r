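# small noiseless stack with one spot per frame at the given column
spot_stack <- function(cols, width = 60, height = 7, row = 4, sigma = 1.2) {
  lapply(cols, function(cx) {
    frame <- matrix(0, height, width)
    for (r in seq_len(height))
      frame[r, ] <- 100 * exp(-((seq_len(width) - cx)^2) / (2 * sigma^2)) *
        exp(-((r - row)^2) / 2)
    frame
  })
}

test_that("a static spot gives a constant horizontal band", {
  st <- spot_stack(rep(25, 10))
  ky <- build_kymograph(st, cbind(c(1, 60), c(4, 4)), line_width = 3)
  expect_s3_class(ky, "kymograph")
  peaks <- apply(ky$data, 2, which.max)
  expect_true(all(peaks == peaks[1]))
})

test_that("a moving spot traces a diagonal of the right slope", {
  st <- spot_stack(10 + 0:19)
  ky <- build_kymograph(st, cbind(c(1, 60), c(4, 4)))
  peaks <- apply(ky$data, 2, which.max)
  expect_equal(diff(peaks), rep(1, 19))
})

test_that("build_kymograph rejects bad paths and line widths", {
  st <- spot_stack(rep(10, 3))
  expect_error(build_kymograph(st, cbind(c(1, 100), c(4, 4))), "bounds")
  expect_error(build_kymograph(st, cbind(c(1, 50), c(4, 4)), line_width = 2),
               "odd")
})

test_that("detection and linking recover clean single and double tracks", {
  st <- spot_stack(10 + 0:19)
  ky <- build_kymograph(st, cbind(c(1, 60), c(4, 4)), pixel_size = 0.5,
                        frame_interval = 1)
  trks <- detect_and_link(ky, detection_threshold = 30, max_jump = 1)
  expect_length(trks, 1)
  expect_equal(nrow(trks[[1]]$samples), 20)

  # two particles far beyond max_jump: two tracks, no identity swaps
  two <- lapply(1:15, function(f) {
    a <- spot_stack(10 + f)[[1]]; b <- spot_stack(45 - f)[[1]]
    a + b
  })
  ky2 <- build_kymograph(two, cbind(c(1, 60), c(4, 4)), pixel_size = 0.5,
                         frame_interval = 1)
  trks2 <- detect_and_link(ky2, 30, max_jump = 1)
  expect_length(trks2, 2)
  drift <- vapply(trks2, function(t) diff(range(t$samples$position_um)),
                  numeric(1))
  expect_true(all(drift < 10))   # a swap would create a large apparent jump

  expect_length(detect_and_link(ky2, detection_threshold = 1e6,
                                max_jump = 1), 0)
})

test_that("a simulated multi-particle movie is recovered track by track", {
  mm <- motility_model(p_mobile = 0.5, p_anterograde = 1, run_speed_sd = 0.03,
                       pause_rate = 0, seed = 21)
  init <- seq(15, 285, by = 30)    # 10 particles, separations >> max_jump
  sim <- simulate_timelapse(300, mm, n_frames = 50, frame_interval = 1,
                            pixel_size = 0.2, n_particles = 10, noise_sd = 2,
                            initial_positions = init)
  ky <- build_kymograph(sim$stack, sim$path, pixel_size = 0.2,
                        frame_interval = 1)
  trks <- detect_and_link(ky, detection_threshold = 30, max_jump = 2)
  expect_gte(length(trks), 9)

  # match each recovered track to the nearest ground-truth particle
  err <- vapply(trks, function(t) {
    i <- which.min(abs(sim$truth$positions[, t$samples$frame[1]] -
                         t$samples$position_um[1]))
    mean(abs(sim$truth$positions[i, t$samples$frame] - t$samples$position_um))
  }, numeric(1))
  expect_lt(mean(err) / 0.2, 0.5)    # mean error under half a pixel
})

test_that("motility classification follows net oriented displacement", {
  flat <- track(1:10, rep(5, 10), frame_interval = 1)
  expect_equal(classify_motility(flat), "stationary")

  fwd <- track(1:10, seq(5, 10, length.out = 10), frame_interval = 1)
  expect_equal(classify_motility(fwd, 2), "anterograde")
  # soma at the high end flips the direction label
  fwd_hi <- track(1:10, seq(5, 10, length.out = 10), frame_interval = 1,
                  soma_end = "high_index")
  expect_equal(classify_motility(fwd_hi, 2), "retrograde")

  # net displacement exactly at threshold counts as mobile
  edge <- track(1:5, c(3, 3.5, 4, 4.5, 5), frame_interval = 1)
  expect_equal(classify_motility(edge, displacement_threshold = 2),
               "anterograde")
  expect_equal(classify_motility(edge, displacement_threshold = 2 + 1e-9),
               "stationary")
})

test_that("run velocities split runs at pauses and report speed", {
  # uniform 0.5 um/s for 20 s
  tr <- track(1:21, 0.5 * (0:20), frame_interval = 1)
  rv <- run_velocities(tr, noise_floor = 0.1)
  expect_equal(nrow(rv), 1)
  expect_equal(rv$velocity_um_s, 0.5)
  expect_equal(rv$direction, "anterograde")

  expect_equal(nrow(run_velocities(track(1:10, rep(2, 10),
                                         frame_interval = 1))), 0)

  # run - pause - run: two runs, pause excluded
  pos <- c(0, 1, 2, 2, 2, 2, 3, 4)
  rv2 <- run_velocities(track(1:8, pos, frame_interval = 1),
                        noise_floor = 0.1)
  expect_equal(nrow(rv2), 2)
  expect_equal(rv2$velocity_um_s, c(1, 1))
})

test_that("summarize_motility aggregates counts and velocities", {
  mk <- function(net) track(1:11, seq(0, net, length.out = 11),
                            frame_interval = 1)
  trks <- c(lapply(c(5, 4, 3), mk), list(mk(-6)),
            lapply(rep(0.2, 6), mk))
  s <- summarize_motility(trks, displacement_threshold = 2,
                          noise_floor = 0.01)
  expect_equal(s$percent_mobile, 40)
  expect_equal(s$percent_anterograde, 75)
  expect_equal(s$percent_retrograde, 25)
  expect_equal(s$mean_velocity_retrograde, 0.6)

  allstat <- summarize_motility(lapply(rep(0.1, 5), mk))
  expect_equal(allstat$percent_mobile, 0)
  expect_true(is.na(allstat$mean_velocity_anterograde))
  expect_error(summarize_motility(list()), "zero tracks")
})

test_that("flipping the path orientation swaps the directional split", {
  mm <- motility_model(p_mobile = 0.6, p_anterograde = 0.7, seed = 33)
  sim <- simulate_timelapse(150, mm, n_frames = 40, frame_interval = 2,
                            pixel_size = 0.2, n_particles = 6, noise_sd = 2)
  ky_lo <- build_kymograph(sim$stack, sim$path, pixel_size = 0.2,
                           frame_interval = 2, soma_end = "low_index")
  ky_hi <- build_kymograph(sim$stack, sim$path, pixel_size = 0.2,
                           frame_interval = 2, soma_end = "high_index")
  s_lo <- summarize_motility(detect_and_link(ky_lo, 30, 2), noise_floor = 0.2)
  s_hi <- summarize_motility(detect_and_link(ky_hi, 30, 2), noise_floor = 0.2)
  expect_equal(s_lo$percent_mobile, s_hi$percent_mobile)
  expect_equal(s_lo$percent_anterograde, s_hi$percent_retrograde)
  expect_equal(s_lo$mean_velocity_anterograde, s_hi$mean_velocity_retrograde)
})

test_that("velocity estimates are invariant to intensity rescaling", {
  st <- spot_stack(10 + 0:19)
  ky <- build_kymograph(st, cbind(c(1, 60), c(4, 4)), pixel_size = 0.5,
                        frame_interval = 1)
  ky2 <- ky; ky2$data <- ky$data * 7.3
  t1 <- detect_and_link(ky, 30, 2)
  t2 <- detect_and_link(ky2, 30 * 7.3, 2)
  expect_equal(t2[[1]]$samples, t1[[1]]$samples, tolerance = 1e-9)
})
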