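# Synthetic behavior-video fixtures with exact ground truth: an anti-aliased
# disk (the "animal") moving over a uniform or gradient background, with
# bounded integer sensor noise, optional interfering objects, and scripted
# stationary (freezing) epochs. Every fixture is reproducible from its spec
# and seed alone, and frames are generated lazily so fixtures never need to
# be stored.

#' Scene specification for a synthetic fixture
#'
#' @param height,width Frame dimensions in pixels.
#' @param n_frames Number of frames.
#' @param fps Frame rate.
#' @param background Constant gray level, or a `height` x `width` matrix
#'   (e.g. a gradient emulating a light-dark arena).
#' @param animal `list(radius =, intensity =)` for the rendered disk, or
#'   `NULL` for an empty arena.
#' @param trajectory Data frame with `x`, `y` (0-based, sub-pixel) and
#'   `n_frames` rows; required when `animal` is given.
#' @param noise_amplitude Integer `a >= 0`: i.i.d. uniform integer sensor
#'   noise on `{-a, ..., a}` added per pixel and frame. Bounded noise keeps
#'   analytic control over thresholds.
#' @param distractor Optional interfering object:
#'   `list(radius =, intensity =, x =, y =, present =)` with per-frame
#'   position vectors and a logical presence vector.
#' @param freeze_script Optional list of half-open frame intervals
#'   `c(start, end)` during which the animal does not move (used by
#'   [make_freeze_fixture()]).
#' @param seed Base RNG seed; per-frame noise seeds derive from it.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, n_frames, fps = 30, background = 245,
                       animal = list(radius = 6, intensity = 20),
                       trajectory = NULL, noise_amplitude = 0,
                       distractor = NULL, freeze_script = NULL, seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_frames >= 1, fps > 0,
            noise_amplitude >= 0, noise_amplitude == floor(noise_amplitude))
  if (is.matrix(background)) {
    stopifnot(nrow(background) == height, ncol(background) == width)
  }
  if (!is.null(animal)) {
    stopifnot(is.list(animal), animal$radius > 0,
              animal$intensity >= 0, animal$intensity <= 255)
    if (is.null(trajectory)) stop("an animal needs a trajectory")
    stopifnot(nrow(trajectory) == n_frames,
              all(c("x", "y") %in% names(trajectory)))
    r <- animal$radius
    if (any(trajectory$x < r) || any(trajectory$x > width - 1 - r) ||
        any(trajectory$y < r) || any(trajectory$y > height - 1 - r)) {
      stop("trajectory leaves the frame (positions must stay a disk radius inside)")
    }
  }
  if (!is.null(distractor)) {
    stopifnot(length(distractor$x) == n_frames,
              length(distractor$y) == n_frames,
              length(distractor$present) == n_frames)
  }
  if (!is.null(freeze_script)) {
    iv <- do.call(rbind, freeze_script)
    if (any(iv[, 1] >= iv[, 2]) || any(iv[, 1] < 0) ||
        any(iv[, 2] > n_frames)) {
      stop("freeze intervals must be half-open [start, end) within the video")
    }
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)])) {
      stop("freeze intervals must not overlap")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), fps = fps,
                 background = background, animal = animal,
                 trajectory = trajectory,
                 noise_amplitude = as.integer(noise_amplitude),
                 distractor = distractor, freeze_script = freeze_script,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Composite an anti-aliased disk (4x supersampled coverage) onto `f`.
composite_disk <- function(f, cx, cy, radius, intensity) {
  h <- nrow(f); w <- ncol(f)
  x0 <- max(0, floor(cx - radius - 2)); x1 <- min(w - 1, ceiling(cx + radius + 2))
  y0 <- max(0, floor(cy - radius - 2)); y1 <- min(h - 1, ceiling(cy + radius + 2))
  ss <- 4L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- x0:x1; ys <- y0:y1
  a <- matrix(0, length(ys), length(xs))
  for (dy in off) for (dx in off) {
    a <- a + (outer((ys + dy - cy)^2, (xs + dx - cx)^2, "+") <= radius^2)
  }
  a <- a / (ss * ss)
  rows <- ys + 1L; cols <- xs + 1L
  f[rows, cols] <- f[rows, cols] * (1 - a) + intensity * a
  f
}

render_frame <- function(spec, i) {
  f <- if (is.matrix(spec$background)) spec$background else
    matrix(spec$background, spec$height, spec$width)
  if (!is.null(spec$animal)) {
    f <- composite_disk(f, spec$trajectory$x[i + 1L], spec$trajectory$y[i + 1L],
                        spec$animal$radius, spec$animal$intensity)
  }
  d <- spec$distractor
  if (!is.null(d) && d$present[i + 1L]) {
    f <- composite_disk(f, d$x[i + 1L], d$y[i + 1L], d$radius, d$intensity)
  }
  a <- spec$noise_amplitude
  if (a > 0) {
    f <- f + with_seed(frame_seed(spec$seed, i),
                       matrix(sample.int(2L * a + 1L, spec$height * spec$width,
                                         replace = TRUE) - a - 1L,
                              spec$height, spec$width))
  }
  pmin(pmax(f, 0), 255)
}

#' Render a scene specification into a fixture with ground truth
#'
#' @param spec A [scene_spec()].
#' @param materialize Render all frames into memory up front (faster when the
#'   fixture is scanned several times) instead of lazily per frame.
#' @return Object of class `fixture_bundle`: `stream` (a `frame_stream`),
#'   `trajectory`, `path_length` (exact sum of Euclidean steps), `spec`, and
#'   for freeze fixtures `freeze_script` and `true_freezing`.
#' @export
render_scene <- function(spec, materialize = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  stream <- if (materialize) {
    as_frame_stream(lapply(seq_len(spec$n_frames) - 1L,
                           function(i) render_frame(spec, i)),
                    fps = spec$fps)
  } else {
    lazy_frame_stream(function(i) render_frame(spec, i),
                      spec$n_frames, spec$height, spec$width, spec$fps)
  }
  path_length <- if (is.null(spec$trajectory)) 0 else
    sum(sqrt(diff(spec$trajectory$x)^2 + diff(spec$trajectory$y)^2))
  structure(list(stream = stream, trajectory = spec$trajectory,
                 path_length = path_length, spec = spec),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d frames %dx%d, path length %.2f px%s\n",
              x$spec$n_frames, x$spec$height, x$spec$width, x$path_length,
              if (!is.null(x$spec$freeze_script))
                sprintf(", %d freeze epochs", length(x$spec$freeze_script))
              else ""))
  invisible(x)
}

#' Circular trajectory at constant speed
#'
#' Starts at angle -pi/2 (directly above the center on screen) and advances
#' `step` pixels of arc per frame.
#'
#' @param n_frames Number of positions.
#' @param cx,cy Circle center (0-based pixels).
#' @param radius Circle radius in pixels.
#' @param step Arc length per frame in pixels.
#' @return Data frame with `x`, `y`.
#' @export
traj_circle <- function(n_frames, cx, cy, radius, step = 2) {
  theta <- -pi / 2 + (seq_len(n_frames) - 1L) * step / radius
  data.frame(x = cx + radius * cos(theta), y = cy + radius * sin(theta))
}

#' Out-and-back linear trajectory
#'
#' Moves `n_out` steps of `step` px in +x, then the same number back,
#' at constant `y`; total path length is exactly `2 * n_out * step`.
#'
#' @param x0,y Start position.
#' @param n_out Steps outward (the trajectory has `2 * n_out + 1` frames).
#' @param step Pixels per frame.
#' @return Data frame with `x`, `y`.
#' @export
traj_out_back <- function(x0, y, n_out, step = 2) {
  x <- c(x0 + step * (0:n_out), x0 + step * ((n_out - 1):0))
  data.frame(x = x, y = rep(y, length(x)))
}

#' Seeded random walk with scripted stationary epochs
#'
#' Constant step length in a uniformly random direction each frame, reflected
#' off the walls of the admissible box; during each scripted interval
#' `[start, end)` the position is held fixed, so the displacement is zero at
#' exactly those frames.
#'
#' @param n_frames Number of positions.
#' @param height,width Frame dimensions (the walk keeps `margin` px inside).
#' @param step Step length in pixels per moving frame.
#' @param freeze_script List of half-open intervals `c(start, end)`.
#' @param margin Wall margin in pixels.
#' @param seed RNG seed.
#' @return Data frame with `x`, `y`.
#' @export
traj_freeze_walk <- function(n_frames, height, width, step = 3,
                             freeze_script = list(), margin = 10, seed = 1L) {
  frozen <- logical(n_frames)
  for (iv in freeze_script) frozen[(iv[1] + 1L):iv[2]] <- TRUE
  lo_x <- margin; hi_x <- width - 1 - margin
  lo_y <- margin; hi_y <- height - 1 - margin
  x <- y <- numeric(n_frames)
  with_seed(seed, {
    x[1] <- runif(1, lo_x, hi_x); y[1] <- runif(1, lo_y, hi_y)
    for (t in 2:n_frames) {
      if (frozen[t]) { x[t] <- x[t - 1]; y[t] <- y[t - 1]; next }
      repeat {
        a <- runif(1, 0, 2 * pi)
        nx <- x[t - 1] + step * cos(a); ny <- y[t - 1] + step * sin(a)
        if (nx >= lo_x && nx <= hi_x && ny >= lo_y && ny <= hi_y) break
      }
      x[t] <- nx; y[t] <- ny
    }
  })
  data.frame(x = x, y = y)
}

#' Fixture with scripted freezing epochs
#'
#' A dark disk performs a constant-speed random walk except during the
#' scripted intervals, where it is pixel-identical across frames up to sensor
#' noise. The returned bundle carries `true_freezing`: the scripted 0/100
#' flags after applying the same minimum-run rule used by
#' [detect_freezing()] (frame 0 has zero displacement by convention).
#'
#' @param height,width,n_frames,fps,seed Scene geometry and seed.
#' @param freeze_script List of half-open frame intervals `c(start, end)`.
#' @param noise_amplitude Integer sensor-noise amplitude.
#' @param step Walk step length per moving frame, in pixels.
#' @param min_freeze_frames Run-length rule applied to the script (should
#'   match the analysis setting).
#' @param background,animal Passed to [scene_spec()].
#' @return A `fixture_bundle` with `freeze_script` and `true_freezing`.
#' @export
make_freeze_fixture <- function(height = 120, width = 160, n_frames = 300,
                                fps = 30, seed = 1L,
                                freeze_script = list(c(45, 95), c(130, 170),
                                                     c(220, 253)),
                                noise_amplitude = 3, step = 3,
                                min_freeze_frames = 15,
                                background = 245,
                                animal = list(radius = 6, intensity = 20)) {
  traj <- traj_freeze_walk(n_frames, height, width, step = step,
                           freeze_script = freeze_script,
                           margin = animal$radius + 4, seed = seed)
  spec <- scene_spec(height, width, n_frames, fps = fps,
                     background = background, animal = animal,
                     trajectory = traj, noise_amplitude = noise_amplitude,
                     freeze_script = freeze_script, seed = seed)
  b <- render_scene(spec)
  # scripted flags under the detector's own conventions: frame 0 counts as
  # zero-displacement, a frame freezes iff its zero-displacement run is long
  # enough
  still <- c(TRUE, diff(traj$x) == 0 & diff(traj$y) == 0)
  r <- rle(still)
  keep <- r$values & r$lengths >= min_freeze_frames
  b$freeze_script <- freeze_script
  b$true_freezing <- as.integer(inverse.rle(list(values = keep,
                                                 lengths = r$lengths))) * 100L
  b
}

# ---- presets: the study conditions used throughout validation -------------

#' Standard validation fixtures
#'
#' Canned scenes with exact ground truth, mirroring the situations the
#' pipelines are validated against:
#'
#' * `fixture_track_loop(seed, noise_amplitude)`: 300-frame 200x400 video, a
#'   dark disk (radius 6, intensity 20 on background 245) moving 2 px/frame
#'   around a circle centered in the frame, starting at the frame center.
#' * `fixture_track_line(seed)`: out-and-back traversal of a fixed 400-px
#'   path at 2 px/frame in a 120x280 frame, sensor noise amplitude 5.
#' * `fixture_track_roi(seed)`: 320-frame circular trajectory plus a
#'   rectangular ROI positioned so that exactly 120 frames (37.5%) fall
#'   inside; noise-free.
#' * `fixture_interference(seed)`: the loop fixture plus an equal-area
#'   distractor disk (contrast 38 gray levels) 150 px from the animal,
#'   present on the second half of the frames.
#' * `fixture_empty(seed, n_frames)`: empty arena with sensor noise
#'   amplitude 3, for motion-threshold calibration.
#'
#' @param seed Base RNG seed.
#' @param noise_amplitude Sensor-noise amplitude for the loop fixture.
#' @param n_frames Frames in the empty-arena fixture.
#' @return A `fixture_bundle`; `fixture_track_roi` additionally carries
#'   `roi` and `true_inside` (0/1 per frame).
#' @name fixture_presets
NULL

#' @rdname fixture_presets
#' @export
fixture_track_loop <- function(seed = 1L, noise_amplitude = 0) {
  traj <- traj_circle(300, cx = 200, cy = 140, radius = 40, step = 2)
  render_scene(scene_spec(200, 400, 300, trajectory = traj,
                          noise_amplitude = noise_amplitude, seed = seed))
}

#' @rdname fixture_presets
#' @export
fixture_track_line <- function(seed = 1L) {
  traj <- traj_out_back(x0 = 40, y = 60, n_out = 100, step = 2)
  render_scene(scene_spec(120, 280, nrow(traj), trajectory = traj,
                          noise_amplitude = 5, seed = seed))
}

#' @rdname fixture_presets
#' @export
fixture_track_roi <- function(seed = 1L) {
  traj <- traj_circle(320, cx = 140, cy = 60, radius = 40, step = 2)
  # rectangle whose x-boundary bisects the gap between the 120 largest and
  # the remaining x positions, so exactly 120 frames are inside
  xs <- sort(traj$x, decreasing = TRUE)
  xcut <- (xs[120] + xs[121]) / 2
  roi <- roi_polygon("east", x = c(xcut, 279, 279, xcut), y = c(0, 0, 119, 119))
  b <- render_scene(scene_spec(120, 280, 320, trajectory = traj,
                               noise_amplitude = 0, seed = seed))
  b$roi <- roi
  b$true_inside <- as.integer(traj$x > xcut)
  b
}

#' @rdname fixture_presets
#' @export
fixture_interference <- function(seed = 1L) {
  n <- 300
  traj <- traj_circle(n, cx = 200, cy = 140, radius = 40, step = 2)
  distractor <- list(radius = 6, intensity = 207,
                     x = traj$x + 150, y = traj$y,
                     present = seq_len(n) > n / 2)
  render_scene(scene_spec(200, 400, n, trajectory = traj,
                          noise_amplitude = 5, distractor = distractor,
                          seed = seed))
}

#' @rdname fixture_presets
#' @export
fixture_empty <- function(seed = 1L, n_frames = 50) {
  render_scene(scene_spec(120, 160, n_frames, animal = NULL,
                          noise_amplitude = 3, seed = seed))
}

#' Materialize a fixture's frames in memory
#'
#' @param bundle A `fixture_bundle`.
#' @return The bundle with an in-memory stream (faster repeated passes).
#' @export
materialize_fixture <- function(bundle) {
  bundle$stream <- as_frame_stream(stream_frames(bundle$stream),
                                   fps = bundle$spec$fps)
  bundle
}
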