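# Freezing analysis: Gaussian-filtered changed-pixel motion counting,
# motion-threshold calibration from an empty-arena video, and freezing
# classification with a minimum-duration rule.

#' Calibrate the motion threshold from an empty-arena video
#'
#' Gaussian-filters every frame, pools the absolute pixel differences of all
#' consecutive frame pairs (the null distribution of grayscale change with no
#' animal present), and suggests `multiplier` times its `percentile`-th
#' percentile as the motion threshold MT.
#'
#' @param empty_stream `frame_stream` of the recording environment without an
#'   animal (>= 2 frames; ~10 s is plenty).
#' @param percentile Percentile of the null distribution (default 99.99).
#' @param multiplier Safety factor on the percentile value (default 2).
#' @param sigma Gaussian filter standard deviation in pixels (default 1).
#' @return Object of class `mt_calibration`: `suggested_MT`,
#'   `percentile_value`, `percentile`, `multiplier`, `sigma`,
#'   `null_distribution` (all pooled values), `n_frames`.
#' @export
calibrate_motion_threshold <- function(empty_stream, percentile = 99.99,
                                       multiplier = 2, sigma = 1) {
  stopifnot(inherits(empty_stream, "frame_stream"))
  n <- empty_stream$meta$frame_count
  if (n < 2) stop("motion-threshold calibration needs at least 2 frames")
  prev <- gaussian_blur(frame_at(empty_stream, 0L), sigma)
  pooled <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    cur <- gaussian_blur(frame_at(empty_stream, t), sigma)
    pooled[[t]] <- as.vector(abs(cur - prev))
    prev <- cur
  }
  pooled <- unlist(pooled)
  pv <- percentile_of(pooled, percentile)
  mt <- multiplier * pv
  if (mt == 0) {
    warning("suggested MT is 0 (perfectly static calibration video)")
  }
  structure(list(suggested_MT = mt, percentile_value = pv,
                 percentile = percentile, multiplier = multiplier,
                 sigma = sigma, null_distribution = pooled,
                 n_frames = n),
            class = "mt_calibration")
}

#' @export
print.mt_calibration <- function(x, ...) {
  cat(sprintf(
    "<mt_calibration> suggested MT = %.4g (= %g x %.4gth percentile of %d null differences, sigma = %g)\n",
    x$suggested_MT, x$multiplier, x$percentile,
    length(x$null_distribution), x$sigma))
  invisible(x)
}

#' @export
plot.mt_calibration <- function(x, breaks = 60, ...) {
  graphics::hist(x$null_distribution, breaks = breaks,
                 main = "Null distribution of pixel grayscale change",
                 xlab = "|filtered frame difference|", ...)
  graphics::abline(v = x$suggested_MT, col = "red", lwd = 2)
  graphics::legend("topright", legend = sprintf("MT = %.3g", x$suggested_MT),
                   col = "red", lwd = 2, bty = "n")
  invisible(x)
}

#' Per-frame motion as changed-pixel counts
#'
#' Motion at frame `t` (t >= 1) is the number of pixels whose
#' Gaussian-filtered grayscale change from the previous frame strictly
#' exceeds the motion threshold `mt`. The first analyzed frame has motion 0
#' by convention.
#'
#' @param stream `frame_stream` (>= 2 frames).
#' @param mt Motion threshold in grayscale-change units (>= 0), typically
#'   from [calibrate_motion_threshold()].
#' @param sigma Gaussian filter standard deviation (default 1).
#' @return A `motion_trace` data frame: `frame`, `motion`.
#' @export
measure_motion <- function(stream, mt, sigma = 1) {
  stopifnot(inherits(stream, "frame_stream"), mt >= 0)
  n <- stream$meta$frame_count
  if (n < 2) stop("motion measurement needs at least 2 frames")
  motion <- integer(n)
  prev <- gaussian_blur(frame_at(stream, 0L), sigma)
  for (t in seq_len(n - 1L)) {
    cur <- gaussian_blur(frame_at(stream, t), sigma)
    motion[t + 1L] <- sum(abs(cur - prev) > mt)
    prev <- cur
  }
  structure(data.frame(frame = stream$meta$first_frame + seq_len(n) - 1L,
                       motion = motion),
            class = c("motion_trace", "data.frame"),
            mt = mt, sigma = sigma, fps = stream$meta$fps)
}

#' Classify freezing from a motion trace
#'
#' Frames with motion strictly below the freezing threshold `ft` are freezing
#' candidates; a frame is scored freezing iff it lies in a maximal run of
#' candidates at least `min_freeze_frames` long.
#'
#' @param trace A `motion_trace` (or data frame with `frame` and `motion`).
#' @param ft Freezing threshold, changed-pixel count (>= 0).
#' @param min_freeze_frames Minimum run length in frames (>= 1); see
#'   [min_duration_frames()] to convert a duration in seconds.
#' @return A `freeze_trace` data frame: `frame`, `motion`, `freezing`
#'   (0 or 100, so that means over bins are percentages).
#' @export
detect_freezing <- function(trace, ft, min_freeze_frames = 1L) {
  stopifnot(ft >= 0, min_freeze_frames >= 1)
  motion <- trace$motion
  cand <- motion < ft
  r <- rle(cand)
  keep <- r$values & r$lengths >= min_freeze_frames
  freezing <- inverse.rle(list(values = keep, lengths = r$lengths))
  structure(data.frame(frame = trace$frame, motion = motion,
                       freezing = as.integer(freezing) * 100L),
            class = c("freeze_trace", "data.frame"),
            ft = ft, min_freeze_frames = as.integer(min_freeze_frames),
            mt = attr(trace, "mt"), sigma = attr(trace, "sigma"),
            fps = attr(trace, "fps"))
}

#' Convert a minimum freeze duration in seconds to frames
#'
#' Rounded to the nearest frame, floored at 1.
#'
#' @param seconds Duration in seconds (e.g. 0.5).
#' @param fps Video frame rate.
#' @return Integer frame count >= 1.
#' @export
min_duration_frames <- function(seconds, fps) {
  stopifnot(seconds >= 0, fps > 0)
  max(1L, as.integer(round(seconds * fps)))
}

#' Percentage of time spent freezing
#'
#' @param trace A `freeze_trace`.
#' @param range Optional [frame_range()] restricting the computation
#'   (0-based positions within the trace).
#' @return Percentage in \[0, 100\].
#' @export
percent_freezing <- function(trace, range = NULL) {
  fr <- trace$freezing
  if (!is.null(range)) {
    stopifnot(inherits(range, "frame_range"))
    if (range$end > length(fr)) stop("range extends beyond the trace")
    fr <- fr[(range$start + 1L):range$end]
  }
  if (length(fr) == 0L) stop("empty frame range")
  mean(fr)
}

#' Measure motion and freezing in one call
#'
#' Convenience wrapper: [measure_motion()] then [detect_freezing()], with the
#' minimum freeze duration given in seconds and converted via the stream's
#' frame rate.
#'
#' @param stream `frame_stream` of the session.
#' @param mt Motion threshold.
#' @param ft Freezing threshold.
#' @param min_duration_sec Minimum freeze duration in seconds (default 0.5).
#' @param sigma Gaussian filter standard deviation (default 1).
#' @param file Label for the `file` column.
#' @return A `freeze_trace` with a `file` column prepended.
#' @export
freeze_session <- function(stream, mt, ft, min_duration_sec = 0.5, sigma = 1,
                           file = NA_character_) {
  trace <- measure_motion(stream, mt, sigma)
  mf <- min_duration_frames(min_duration_sec, stream$meta$fps)
  out <- detect_freezing(trace, ft, mf)
  out <- cbind(data.frame(file = if (is.na(file) && !is.na(stream$meta$path))
    basename(stream$meta$path) else file, stringsAsFactors = FALSE), out)
  structure(out, class = c("freeze_trace", "data.frame"),
            ft = ft, min_freeze_frames = mf, mt = mt, sigma = sigma,
            fps = stream$meta$fps)
}

#' @export
print.freeze_trace <- function(x, ...) {
  cat(sprintf("<freeze_trace> %d frames, %.1f%% freezing\n",
              nrow(x), mean(x$freezing)))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.freeze_trace <- function(object, ...) {
  structure(list(n_frames = nrow(object),
                 mean_motion = mean(object$motion),
                 percent_freezing = mean(object$freezing),
                 n_bouts = sum(rle(object$freezing > 0)$values)),
            class = "summary.freeze_trace")
}

#' @export
print.summary.freeze_trace <- function(x, ...) {
  cat(sprintf("%d frames; mean motion %.1f px; %.1f%% freezing in %d bouts\n",
              x$n_frames, x$mean_motion, x$percent_freezing, x$n_bouts))
  invisible(x)
}
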