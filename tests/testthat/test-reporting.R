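# Binned summaries, conservation, CSV/batch behavior, plot files.

make_tracked_loop <- function(seed = 61, n = 120) {
  traj <- traj_circle(n, 60, 60, 25, step = 1)
  b <- render_scene(scene_spec(120, 120, n, trajectory = traj,
                               noise_amplitude = 0, seed = seed))
  roi <- roi_polygon("east", x = c(60, 119, 119, 60), y = c(0, 0, 119, 119))
  track_session(b$stream, params = location_params(), rois = list(roi),
                calibration = calibrate_scale(c(0, 0), c(100, 0), 50, "cm"),
                file = "loop")
}

test_that("binned distances follow the first-frame-step convention", {
  # constant 1 px/frame: a bin containing frame 0 sums to its length - 1
  tr <- make_tracked_loop()
  bins <- bin_spec(c("a", "b"), c(0, 100), c(100, 120))
  s <- summarize_bins(tr, bins)
  expect_equal(s$distance_px[1], sum(tr$distance_px[1:100]))
  expect_equal(s$distance_px[1], 99, tolerance = 0.01)
  expect_equal(s$distance_px[2], 20, tolerance = 0.01)
  expect_equal(s$distance_cm, s$distance_px * 0.5)
  expect_error(summarize_bins(tr, bin_spec("late", 100, 200)), "late")
})

test_that("non-overlapping bins tiling the session conserve totals exactly", {
  tr <- make_tracked_loop(seed = 62)
  cuts <- c(0, 13, 40, 77, 120)
  bins <- bin_spec(paste0("b", 1:4), cuts[-5], cuts[-1])
  s <- summarize_bins(tr, bins)
  expect_equal(sum(s$distance_px), sum(tr$distance_px))
  expect_equal(sum(s$n_frames * s$prop_east), sum(tr$east))
  expect_identical(sum(s$n_frames), nrow(tr))
})

test_that("ROI proportions and freezing percentages summarize per bin", {
  tr <- make_tracked_loop(seed = 63)
  # a bin holding equal frames in and out of the half-plane ROI
  inside <- tr$east
  s <- summarize_bins(tr, bin_spec("all", 0, 120))
  expect_equal(s$prop_east, mean(inside))
  b <- make_freeze_fixture(seed = 64)
  st <- materialize_fixture(b)$stream
  fz <- freeze_session(st, mt = 6, ft = 60, file = "fz")
  sf <- summarize_bins(fz, bin_spec(c("x", "y"), c(0, 100), c(100, 300)))
  expect_equal(sf$percent_freezing[1], mean(fz$freezing[1:100]))
  expect_equal(sf$mean_motion[2], mean(fz$motion[101:300]))
  all100 <- which(fz$freezing == 100)
  run <- all100[1]:(all100[1] + 9)
  s1 <- summarize_bins(fz, bin_spec("run", run[1] - 1, run[10]))
  expect_equal(s1$percent_freezing, 100)
})

test_that("seconds-based bins tile the session with a flagged partial tail", {
  bins <- bins_by_seconds(1, fps = 30, n_frames = 100)
  expect_equal(nrow(bins), 4)
  expect_equal(bins$end[4], 100)
  tr <- make_tracked_loop(seed = 65, n = 100)
  s <- summarize_bins(tr, bins)
  expect_identical(s$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(s$n_frames[4], 10)
})

test_that("the occupancy heatmap conserves the analyzed frame count", {
  tr <- make_tracked_loop(seed = 66)
  expect_equal(sum(occupancy_heatmap(tr)), nrow(tr))
  expect_equal(sum(occupancy_heatmap(tr, bin_px = 10)), nrow(tr))
})

test_that("summary plots are written as non-empty files", {
  tr <- make_tracked_loop(seed = 67)
  out <- withr::local_tempdir()
  files <- make_plots(tr, out, prefix = "loop")
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 1000))
  b <- make_freeze_fixture(seed = 68)
  fz <- freeze_session(materialize_fixture(b)$stream, mt = 6, ft = 60)
  ff <- make_plots(fz, out, prefix = "fz")
  expect_true(file.exists(ff) && file.size(ff) > 1000)
  emp <- fixture_empty(seed = 69, n_frames = 10)
  cal <- calibrate_motion_threshold(emp$stream)
  cf <- make_plots(cal, out, prefix = "cal")
  expect_true(file.exists(cf) && file.size(cf) > 1000)
})

write_fixture_videos <- function(root, seeds) {
  for (s in seeds) {
    traj <- traj_circle(40, 60, 60, 20, step = 2)
    b <- render_scene(scene_spec(120, 120, 40, trajectory = traj,
                                 noise_amplitude = 0, seed = s))
    write_video(b$stream, file.path(root, sprintf("mouse%02d", s)))
  }
}

test_that("batch processing writes per-video CSVs, a summary, and a log", {
  root <- withr::local_tempdir(); out <- file.path(root, "out")
  write_fixture_videos(root, 1:3)
  cfg <- batch_config(root, out, bins = 1)
  res <- run_batch(cfg, "location",
                   params = location_params(reference_sample_n = 40))
  expect_length(res$outputs, 3)
  expect_true(all(file.exists(res$outputs)))
  expect_length(res$failures, 0)
  smry <- read.csv(res$summary)
  expect_setequal(unique(smry$file), c("mouse01", "mouse02", "mouse03"))
  expect_true(file.exists(res$log))
})

test_that("a corrupt video is logged without aborting the batch", {
  root <- withr::local_tempdir(); out <- file.path(root, "out")
  write_fixture_videos(root, 1:2)
  bad <- file.path(root, "broken")
  dir.create(bad)
  writeLines("{", file.path(bad, "behavtrack_video.json"))
  expect_warning(
    res <- run_batch(batch_config(root, out), "location",
                     params = location_params(reference_sample_n = 40)),
    "1 of 3")
  expect_length(res$outputs, 2)
  expect_equal(names(res$failures), "broken")
  expect_match(paste(readLines(res$log), collapse = "\n"), "FAILED: broken")
  expect_error(run_batch(batch_config(file.path(root, "empty2"), out)),
               "does not exist")
})

test_that("batch output is deterministic and equals single-file processing", {
  root <- withr::local_tempdir()
  write_fixture_videos(root, 7)
  p <- location_params(reference_sample_n = 30, rng_seed = 3)
  out1 <- file.path(root, "o1"); out2 <- file.path(root, "o2")
  r1 <- run_batch(batch_config(root, out1), "location", params = p)
  r2 <- run_batch(batch_config(root, out2), "location", params = p)
  expect_identical(readBin(r1$outputs[1], "raw", 1e6),
                   readBin(r2$outputs[1], "raw", 1e6))
  # single-file processing with the same parameters is byte-identical
  s <- open_video(file.path(root, "mouse07"))
  tr <- track_session(s, params = p)
  single <- file.path(root, "single.csv")
  write_result_csv(tr, single)
  expect_identical(readBin(single, "raw", 1e6),
                   readBin(r1$outputs[1], "raw", 1e6))
})
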