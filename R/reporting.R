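# Time-binned summaries, CSV writers, and static summary plots.

#' Time-bin specification
#'
#' Bins are half-open frame-index intervals `[start, end)` against the
#' `frame` column of a result; they may overlap, and labels must be unique.
#'
#' @param labels Character vector of unique bin labels.
#' @param start,end Integer vectors of half-open frame bounds.
#' @param nominal Intended bin length in frames (defaults to `end - start`);
#'   a bin realizing fewer frames than its nominal length is flagged partial
#'   in summaries.
#' @return A `bin_spec` data frame with columns `label`, `start`, `end`,
#'   `nominal`.
#' @export
bin_spec <- function(labels, start, end, nominal = NULL) {
  stopifnot(length(labels) == length(start), length(start) == length(end))
  if (anyDuplicated(labels)) stop("bin labels must be unique")
  if (any(start >= end)) stop("each bin needs start < end")
  if (is.null(nominal)) nominal <- end - start
  structure(data.frame(label = as.character(labels),
                       start = as.integer(start), end = as.integer(end),
                       nominal = as.integer(nominal),
                       stringsAsFactors = FALSE),
            class = c("bin_spec", "data.frame"))
}

#' Tile a session into fixed-duration time bins
#'
#' Converts seconds to frames via the frame rate (half-open bins); a partial
#' trailing bin is kept and carries its true frame count in the summary.
#'
#' @param bin_seconds Bin duration in seconds.
#' @param fps Frame rate.
#' @param n_frames Number of analyzed frames.
#' @param first_frame Index of the first analyzed frame.
#' @return A `bin_spec`.
#' @export
bins_by_seconds <- function(bin_seconds, fps, n_frames, first_frame = 0L) {
  stopifnot(bin_seconds > 0, fps > 0, n_frames >= 1)
  w <- max(1L, as.integer(round(bin_seconds * fps)))
  starts <- seq.int(0L, n_frames - 1L, by = w)
  ends <- pmin(starts + w, n_frames)
  bin_spec(sprintf("%g-%gs", starts / fps, ends / fps),
           first_frame + starts, first_frame + ends, nominal = w)
}

#' Summarize a result over time bins
#'
#' For tracking results: distance traveled (pixels, and physical units when
#' calibrated) and the proportion of frames spent in each ROI, per bin. For
#' freeze traces: mean motion and percent freezing per bin. The first frame's
#' step distance (0 by convention) belongs to the bin containing it, so
#' non-overlapping bins that tile the session sum exactly to whole-session
#' totals.
#'
#' @param result A `tracking_result` or `freeze_trace`.
#' @param bins A [bin_spec()]; every bin must lie inside the analyzed range.
#' @return A `session_summary` data frame, one row per bin.
#' @export
summarize_bins <- function(result, bins) {
  UseMethod("summarize_bins")
}

check_bins <- function(bins, frames) {
  stopifnot(inherits(bins, "bin_spec"))
  lo <- min(frames); hi <- max(frames) + 1L
  bad <- bins$start < lo | bins$end > hi
  if (any(bad)) {
    stop(sprintf("bin '%s' [%d, %d) outside analyzed frames [%d, %d)",
                 bins$label[bad][1], bins$start[bad][1], bins$end[bad][1],
                 lo, hi))
  }
}

bin_rows <- function(bins, frames) {
  lapply(seq_len(nrow(bins)), function(i)
    which(frames >= bins$start[i] & frames < bins$end[i]))
}

#' @rdname summarize_bins
#' @export
summarize_bins.tracking_result <- function(result, bins) {
  check_bins(bins, result$frame)
  rows <- bin_rows(bins, result$frame)
  cal <- attr(result, "calibration")
  rois <- attr(result, "rois")
  out <- data.frame(file = result$file[1], bin = bins$label,
                    start = bins$start, end = bins$end,
                    n_frames = lengths(rows),
                    partial = lengths(rows) < bins$nominal,
                    distance_px = vapply(rows, function(r)
                      sum(result$distance_px[r]), numeric(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(cal)) {
    col <- paste0("distance_", cal$unit_label)
    out[[col]] <- vapply(rows, function(r) sum(result[[col]][r]), numeric(1))
  }
  for (r in rois) {
    out[[paste0("prop_", r$name)]] <- vapply(rows, function(rw)
      mean(result[[r$name]][rw]), numeric(1))
  }
  structure(out, class = c("session_summary", "data.frame"))
}

#' @rdname summarize_bins
#' @export
summarize_bins.freeze_trace <- function(result, bins) {
  check_bins(bins, result$frame)
  rows <- bin_rows(bins, result$frame)
  out <- data.frame(
    file = if ("file" %in% names(result)) result$file[1] else NA_character_,
    bin = bins$label, start = bins$start, end = bins$end,
    n_frames = lengths(rows),
    partial = lengths(rows) < bins$end - bins$start,
    mean_motion = vapply(rows, function(r) mean(result$motion[r]), numeric(1)),
    percent_freezing = vapply(rows, function(r)
      mean(result$freezing[r]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(out, class = c("session_summary", "data.frame"))
}

#' Write a frame-by-frame or summary CSV
#'
#' Plain comma-separated UTF-8 with a header row, `.` decimal separator and
#' no row names, so repeated runs with the same inputs are byte-identical.
#'
#' @param x Data frame to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
plot.tracking_result <- function(x, type = c("trajectory", "heatmap",
                                             "distance"), bin_px = 8, ...) {
  type <- match.arg(type)
  ref <- ref_image(attr(x, "reference"))
  if (type == "trajectory") {
    image(t(ref)[, nrow(ref):1], col = gray.colors(64, 0, 1), axes = FALSE,
          main = "Trajectory over reference frame", useRaster = TRUE)
    # map pixel coords to [0,1] plot coords
    px <- (x$x + 0.5) / ncol(ref); py <- 1 - (x$y + 0.5) / nrow(ref)
    lines(px, py, col = "red")
    points(px[1], py[1], col = "blue", pch = 16)
  } else if (type == "heatmap") {
    hm <- occupancy_heatmap(x, bin_px = bin_px)
    image(t(hm)[, nrow(hm):1], col = hcl.colors(32, "inferno"), axes = FALSE,
          main = "Occupancy heatmap", useRaster = TRUE)
  } else {
    plot(x$frame, x$distance_px, type = "l", xlab = "frame",
         ylab = "distance (px)", main = "Distance per frame", ...)
  }
  invisible(x)
}

#' @export
plot.freeze_trace <- function(x, ...) {
  plot(x$frame, x$motion, type = "n", xlab = "frame",
       ylab = "motion (changed pixels)", main = "Motion and freezing", ...)
  fr <- x$freezing > 0
  if (any(fr)) {
    r <- rle(fr)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rect(x$frame[starts[k]], par("usr")[3], x$frame[ends[k]],
           par("usr")[4], col = "gray85", border = NA)
    }
  }
  lines(x$frame, x$motion, col = "blue")
  ft <- attr(x, "ft")
  if (!is.null(ft)) abline(h = ft, col = "red", lty = 2)
  invisible(x)
}

#' Write static summary plots for a result
#'
#' Tracking results get a trajectory-over-reference plot, an occupancy
#' heatmap and a distance trace; freeze traces get a motion trace with
#' freezing epochs shaded; calibrations get the null-distribution histogram.
#'
#' @param result A `tracking_result`, `freeze_trace`, or `mt_calibration`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of written file paths.
#' @export
make_plots <- function(result, out_dir, prefix = "session") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create plot directory ", out_dir)
  save_png <- function(name, expr) {
    f <- file.path(out_dir, paste0(prefix, "_", name, ".png"))
    grDevices::png(f, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    force(expr)
    f
  }
  if (inherits(result, "tracking_result")) {
    c(save_png("trajectory", plot(result, type = "trajectory")),
      save_png("heatmap", plot(result, type = "heatmap")),
      save_png("distance", plot(result, type = "distance")))
  } else if (inherits(result, "freeze_trace")) {
    save_png("motion", plot(result))
  } else if (inherits(result, "mt_calibration")) {
    save_png("mt_histogram", plot(result))
  } else {
    stop("don't know how to plot an object of class ", class(result)[1])
  }
}
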