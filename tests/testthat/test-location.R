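# Location tracking: median reference, differencing, percentile threshold,
# window weighting, center of mass, ROIs, scale calibration, full sessions.

test_that("the median reference matches a brute-force sort-and-middle oracle", {
  # constant video
  s <- mat_stream(lapply(1:6, function(i) matrix(42, 4, 4)))
  expect_identical(make_reference(s)$image, matrix(42, 4, 4))
  # animal passes through pixel (0,0) once
  vals <- c(10, 10, 10, 200, 10)
  frames <- lapply(vals, function(v) matrix(c(v, 7, 3, 9), 2, 2))
  ref <- make_reference(mat_stream(frames))
  expect_equal(ref$image[1, 1], 10)
  expect_identical(ref$image, oracle_median_stack(frames))
  # random stacks, odd and even counts
  set.seed(21)
  for (n in c(5, 8)) {
    frames <- lapply(seq_len(n), function(i)
      matrix(sample(0:255, 25, TRUE), 5, 5))
    expect_identical(make_reference(mat_stream(frames))$image,
                     oracle_median_stack(frames))
  }
})

test_that("reference sampling uses 100 seeded frames by default and records provenance", {
  frames <- lapply(1:150, function(i) matrix(i %% 7, 3, 3))
  s <- mat_stream(frames)
  r1 <- make_reference(s, location_params(rng_seed = 5))
  r2 <- make_reference(s, location_params(rng_seed = 5))
  r3 <- make_reference(s, location_params(rng_seed = 6))
  expect_length(r1$sample_indices, 100)
  expect_true(all(r1$sample_indices >= 0 & r1$sample_indices < 150))
  expect_identical(r1$sample_indices, r2$sample_indices)
  expect_false(identical(r1$sample_indices, r3$sample_indices))
  expect_equal(r1$source, "same_video")
  expect_equal(r1$rng_seed, 5L)
})

test_that("reference recovers the background exactly under <50% occlusion", {
  # 20x20 arena, disk occludes each pixel in fewer than half the frames
  traj <- data.frame(x = seq(4, 15, length.out = 30),
                     y = seq(4, 15, length.out = 30))
  spec <- scene_spec(20, 20, 30, background = 200,
                     animal = list(radius = 3, intensity = 30),
                     trajectory = traj, noise_amplitude = 0, seed = 1)
  b <- render_scene(spec)
  ref <- make_reference(b$stream, location_params(reference_sample_n = 30))
  expect_identical(ref$image, matrix(200, 20, 20))
})

test_that("an external empty-arena stream replaces the session for the reference", {
  sess <- mat_stream(lapply(1:5, function(i) matrix(50, 4, 4)))
  ext <- mat_stream(lapply(1:4, function(i) matrix(9, 4, 4)))
  ref <- make_reference(sess, external_stream = ext)
  expect_identical(ref$image, matrix(9, 4, 4))
  expect_equal(ref$source, "external_video")
  bad <- mat_stream(list(matrix(9, 3, 4)))
  expect_error(make_reference(sess, external_stream = bad), "dimensions")
})

test_that("frame differencing follows the three contrast modes", {
  f <- matrix(c(10, 30, 20, 40), 2, 2, byrow = TRUE)
  ref <- matrix(20, 2, 2)
  expect_identical(frame_difference(f, ref, "absolute"),
                   matrix(c(10, 10, 0, 20), 2, 2, byrow = TRUE))
  expect_identical(frame_difference(f, ref, "animal_darker"),
                   matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_identical(frame_difference(f, ref, "animal_lighter"),
                   matrix(c(0, 10, 0, 20), 2, 2, byrow = TRUE))
  expect_identical(frame_difference(ref, ref, "absolute"), matrix(0, 2, 2))
  expect_error(frame_difference(matrix(0, 2, 3), ref), "dimensions")
})

test_that("percentile thresholding keeps only values strictly above the cutoff", {
  m <- matrix(sample(1:100), 10, 10)
  out <- threshold_by_percentile(m, 99)
  # cutoff is 99.01 under linear interpolation, so only 100 survives
  expect_equal(sum(out > 0), 1)
  expect_equal(max(out), 100)
  # all-equal input: cutoff equals the common value, everything zeroed
  expect_identical(threshold_by_percentile(matrix(5, 4, 4), 99),
                   matrix(0, 4, 4))
  # oracle equivalence on random matrices
  set.seed(22)
  for (trial in 1:100) {
    m <- matrix(runif(400, 0, 50), 20, 20)
    p <- sample(c(50, 90, 99, 99.9), 1)
    expect_identical(threshold_by_percentile(m, p), oracle_threshold(m, p))
  }
})

test_that("window weighting scales outside pixels by 1 - omega and clips at edges", {
  m <- matrix(50, 9, 9)
  expect_identical(apply_location_weight(m, c(4, 4), 3, 0), m)
  w1 <- apply_location_weight(m, c(4, 4), 3, 1)
  expect_true(all(w1[4:6, 4:6] == 50))
  expect_true(all(w1[-(4:6), ] == 0) && all(w1[, -(4:6)] == 0))
  w8 <- apply_location_weight(m, c(4, 4), 3, 0.8)
  expect_equal(w8[5, 5], 50)
  expect_equal(w8[1, 1], 10)
  # window centered near a corner is clipped, not wrapped
  wc <- apply_location_weight(m, c(0, 0), 5, 1)
  expect_true(all(wc[1:3, 1:3] == 50))
  expect_equal(sum(wc > 0), 9)
})

test_that("center of mass is the intensity-weighted mean pixel coordinate", {
  m <- matrix(0, 8, 8); m[6, 4] <- 7  # x = 3, y = 5 (0-based)
  expect_equal(center_of_mass(m), c(3, 5))
  m2 <- matrix(0, 3, 5); m2[1, 1] <- 2; m2[1, 3] <- 2
  expect_equal(center_of_mass(m2), c(1, 0))
  m3 <- matrix(0, 2, 5); m3[1, 1] <- 1; m3[1, 5] <- 3
  expect_equal(center_of_mass(m3), c(3, 0))
  # all-zero: falls back with a warning
  expect_warning(p <- center_of_mass(matrix(0, 4, 4), fallback = c(1, 2)),
                 "all-zero")
  expect_equal(p, c(1, 2))
  # oracle equivalence on random matrices
  set.seed(23)
  for (trial in 1:100) {
    m <- matrix(runif(400), 20, 20)
    expect_equal(center_of_mass(m), oracle_com(m))
  }
})

test_that("point-in-ROI uses the even-odd rule with boundary counted inside", {
  sq <- roi_polygon("sq", x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  expect_true(point_in_roi(c(5, 5), sq))
  expect_false(point_in_roi(c(20, 20), sq))
  expect_true(point_in_roi(c(5, 0), sq))   # on an edge
  expect_true(point_in_roi(c(10, 10), sq)) # on a vertex
  # non-convex polygon (L shape)
  ell <- roi_polygon("ell", x = c(0, 4, 4, 2, 2, 0), y = c(0, 0, 2, 2, 4, 4))
  expect_true(point_in_roi(c(1, 3), ell))
  expect_false(point_in_roi(c(3, 3), ell))
  expect_error(roi_polygon("bad", x = c(0, 1, 2), y = c(0, 1, 2)), "degenerate")
  # interior agreement with an independent implementation
  set.seed(24)
  pts <- cbind(runif(200, -1, 5), runif(200, -1, 5))
  mine <- apply(pts, 1, function(p) point_in_roi(p, ell))
  theirs <- as.logical(mgcv::in.out(cbind(c(ell$x, ell$x[1]),
                                          c(ell$y, ell$y[1])), pts))
  expect_identical(mine, theirs)
})

test_that("scale calibration converts pixels to physical units", {
  cal <- calibrate_scale(c(0, 0), c(100, 0), 200, "cm")
  expect_equal(cal$factor, 2)
  expect_equal(calibrate_scale(c(0, 0), c(3, 4), 5)$factor, 1)
  expect_error(calibrate_scale(c(1, 1), c(1, 1), 10), "distinct")
  expect_error(calibrate_scale(c(0, 0), c(1, 0), -1), "positive")
})

test_that("a stationary noise-free disk tracks to zero total distance", {
  traj <- data.frame(x = rep(60, 50), y = rep(50, 50))
  b <- render_scene(scene_spec(120, 150, 50, trajectory = traj,
                               noise_amplitude = 0, seed = 1))
  # a parked animal dominates the median, so use an external empty reference
  empty <- render_scene(scene_spec(120, 150, 10, animal = NULL,
                                   noise_amplitude = 0, seed = 1))
  ref <- make_reference(b$stream, external_stream = empty$stream)
  tr <- track_session(b$stream, reference = ref)
  expect_equal(sum(tr$distance_px), 0)
  expect_lt(max(tracking_error(tr, b)), 0.1)
})

test_that("a moving disk is tracked to sub-pixel accuracy with exact distances", {
  b <- fixture_track_loop(seed = 31, noise_amplitude = 0)
  tr <- track_session(b$stream, params = location_params())
  expect_lt(max(tracking_error(tr, b)), 0.5)
  expect_lt(abs(sum(tr$distance_px) - b$path_length) / b$path_length, 0.02)
  expect_equal(tr$distance_px[1], 0)
  expect_equal(nrow(tr), 300)
  expect_identical(tr$frame, 0:299)
})

test_that("calibrated distances are an exact multiple of pixel distances", {
  b <- fixture_track_loop(seed = 32, noise_amplitude = 0)
  cal <- calibrate_scale(c(0, 0), c(0, 100), 200, "cm")
  tr <- track_session(b$stream, params = location_params(), calibration = cal)
  expect_identical(tr$distance_cm, tr$distance_px * 2)
})

test_that("tracking is symmetric under contrast polarity inversion", {
  b <- fixture_track_loop(seed = 33, noise_amplitude = 0)
  frames <- stream_frames(b$stream)
  inv <- mat_stream(lapply(frames, function(f) 255 - f))
  p <- location_params()
  t1 <- track_session(mat_stream(frames), params = p)
  t2 <- track_session(inv, params = p)
  expect_lt(max(abs(t1$x - t2$x)), 0.5)
  expect_lt(max(abs(t1$y - t2$y)), 0.5)
})

test_that("halving global illumination leaves the trajectory unchanged", {
  # the percentile cutoff scales with the frame's own difference distribution
  b <- fixture_track_loop(seed = 34, noise_amplitude = 0)
  frames <- stream_frames(b$stream)
  dim1 <- mat_stream(lapply(frames, function(f) f * 0.5))
  t1 <- track_session(mat_stream(frames), params = location_params())
  t2 <- track_session(dim1, params = location_params())
  expect_lt(max(sqrt((t1$x - t2$x)^2 + (t1$y - t2$y)^2)), 0.5)
})

test_that("distance is invariant under rigid transforms of the trajectory", {
  traj <- traj_circle(100, cx = 60, cy = 60, radius = 25, step = 2)
  rot <- data.frame(x = 60 - (traj$y - 60), y = 60 + (traj$x - 60))  # 90 deg
  shift <- data.frame(x = traj$x + 15, y = traj$y - 10)
  total <- function(tj) {
    b <- render_scene(scene_spec(120, 120, 100, trajectory = tj,
                                 noise_amplitude = 0, seed = 2))
    sum(track_session(b$stream, params = location_params())$distance_px)
  }
  d0 <- total(traj); d1 <- total(rot); d2 <- total(shift)
  expect_lt(abs(d1 - d0) / d0, 0.01)
  expect_lt(abs(d2 - d0) / d0, 0.01)
})

test_that("ROI occupancy flags come from per-frame center-of-mass membership", {
  b <- fixture_track_roi(seed = 35)
  tr <- track_session(b$stream, params = location_params(), rois = list(b$roi))
  expect_identical(tr$east, b$true_inside)
  expect_equal(mean(tr$east), 0.375)
})
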