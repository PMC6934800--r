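# Frame streams: lazy access to grayscale video frames with cropping,
# frame-range restriction and spatial downsampling. A "video" on disk is a
# lossless image-sequence directory: 8-bit grayscale PNG frames
# (frame_000000.png, ...) plus a JSON metadata sidecar giving the frame rate.
# Streams never hold more than one decoded frame at a time.

VIDEO_SIDECAR <- "behavtrack_video.json"

#' Rectangular crop region
#'
#' Pixel coordinates are 0-based with `x` the column and `y` the row; the
#' region is half-open, so `crop_region(0, 0, w, h)` is the full frame.
#'
#' @param x0,y0 Top-left pixel (inclusive).
#' @param x1,y1 Bottom-right pixel (exclusive).
#' @return An object of class `crop_region`.
#' @export
crop_region <- function(x0, y0, x1, y1) {
  vals <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(vals != floor(vals)) || any(vals < 0)) {
    stop("crop coordinates must be non-negative integers")
  }
  if (!(x0 < x1 && y0 < y1)) {
    stop("invalid crop region: need x0 < x1 and y0 < y1")
  }
  structure(as.list(as.integer(vals)), names = names(vals), class = "crop_region")
}

#' Frame range
#'
#' Half-open range of 0-based frame indices `[start, end)`.
#'
#' @param start First frame (inclusive, 0-based).
#' @param end One past the last frame (exclusive).
#' @return An object of class `frame_range`.
#' @export
frame_range <- function(start, end) {
  if (start != floor(start) || end != floor(end) || start < 0 || start >= end) {
    stop("invalid frame range: need 0 <= start < end")
  }
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "frame_range")
}

new_frame_stream <- function(frame_fn, n_frames, height, width, fps,
                             first_frame = 0L, path = NA_character_) {
  stopifnot(fps > 0, n_frames >= 1, height >= 1, width >= 1)
  structure(list(
    meta = list(path = path, fps = fps, frame_count = as.integer(n_frames),
                height = as.integer(height), width = as.integer(width),
                first_frame = as.integer(first_frame)),
    frame_fn = frame_fn
  ), class = "frame_stream")
}

#' Construct a lazy frame stream from a generating function
#'
#' @param frame_fn Function taking a 0-based frame index and returning a
#'   `height` x `width` numeric matrix with values in `[0, 255]`.
#' @param n_frames,height,width,fps Stream geometry and frame rate.
#' @return A `frame_stream`.
#' @export
lazy_frame_stream <- function(frame_fn, n_frames, height, width, fps = 30) {
  new_frame_stream(frame_fn, n_frames, height, width, fps)
}

#' Wrap in-memory frames as a frame stream
#'
#' @param x A list of equally sized numeric matrices, or a 3-D array with
#'   dimensions height x width x frames.
#' @param fps Frames per second.
#' @return A `frame_stream`.
#' @export
as_frame_stream <- function(x, fps = 30) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  }
  stopifnot(is.list(x), length(x) >= 1L, all(vapply(x, is.matrix, TRUE)))
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions")
  }
  new_frame_stream(function(i) x[[i + 1L]], length(x),
                   nrow(x[[1]]), ncol(x[[1]]), fps)
}

#' Read one frame from a stream
#'
#' @param stream A `frame_stream`.
#' @param i 0-based frame index within the stream.
#' @return Numeric matrix (grayscale, values in `[0, 255]`).
#' @export
frame_at <- function(stream, i) {
  stopifnot(inherits(stream, "frame_stream"))
  if (i < 0 || i >= stream$meta$frame_count) {
    stop(sprintf("frame index %d outside [0, %d)", i, stream$meta$frame_count))
  }
  stream$frame_fn(as.integer(i))
}

#' Materialize every frame of a stream into a list
#'
#' Convenience for tests and small fixtures; defeats the streaming memory
#' bound on long videos.
#'
#' @inheritParams frame_at
#' @return List of matrices, one per frame.
#' @export
stream_frames <- function(stream) {
  lapply(seq_len(stream$meta$frame_count) - 1L, function(i) frame_at(stream, i))
}

#' @export
print.frame_stream <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<frame_stream> %d frames, %dx%d px, %.6g fps%s\n",
              m$frame_count, m$height, m$width, m$fps,
              if (!is.na(m$path)) paste0(", ", m$path) else ""))
  invisible(x)
}

#' Restrict a stream to a frame range
#'
#' @param stream A `frame_stream`.
#' @param range A [frame_range()] within the stream.
#' @return A `frame_stream` yielding only the selected frames.
#' @export
stream_range <- function(stream, range) {
  stopifnot(inherits(stream, "frame_stream"), inherits(range, "frame_range"))
  n <- stream$meta$frame_count
  if (range$end > n) {
    stop(sprintf("frame range [%d, %d) outside video with %d frames",
                 range$start, range$end, n))
  }
  base_fn <- stream$frame_fn
  new_frame_stream(function(i) base_fn(i + range$start),
                   range$end - range$start,
                   stream$meta$height, stream$meta$width, stream$meta$fps,
                   first_frame = stream$meta$first_frame + range$start,
                   path = stream$meta$path)
}

#' Crop every frame of a stream
#'
#' @param stream A `frame_stream`.
#' @param crop A [crop_region()] within the frame bounds.
#' @return A `frame_stream` of cropped frames.
#' @export
stream_crop <- function(stream, crop) {
  stopifnot(inherits(stream, "frame_stream"), inherits(crop, "crop_region"))
  h <- stream$meta$height; w <- stream$meta$width
  if (crop$x1 > w || crop$y1 > h) {
    stop(sprintf("crop region (%d,%d)-(%d,%d) outside %dx%d frame",
                 crop$x0, crop$y0, crop$x1, crop$y1, w, h))
  }
  rows <- (crop$y0 + 1L):crop$y1
  cols <- (crop$x0 + 1L):crop$x1
  base_fn <- stream$frame_fn
  new_frame_stream(function(i) base_fn(i)[rows, cols, drop = FALSE],
                   stream$meta$frame_count, length(rows), length(cols),
                   stream$meta$fps, stream$meta$first_frame, stream$meta$path)
}

#' Spatially downsample every frame of a stream
#'
#' Bilinear resampling by a positive real factor, applied after any crop.
#'
#' @param stream A `frame_stream`.
#' @param factor Scale factor (> 0); 0.5 halves both dimensions.
#' @return A `frame_stream` of resampled frames.
#' @export
stream_downsample <- function(stream, factor) {
  stopifnot(inherits(stream, "frame_stream"), factor > 0)
  nh <- max(1L, as.integer(round(stream$meta$height * factor)))
  nw <- max(1L, as.integer(round(stream$meta$width * factor)))
  base_fn <- stream$frame_fn
  new_frame_stream(function(i) resize_bilinear(base_fn(i), factor),
                   stream$meta$frame_count, nh, nw,
                   stream$meta$fps, stream$meta$first_frame, stream$meta$path)
}

read_sidecar <- function(path) {
  sc <- file.path(path, VIDEO_SIDECAR)
  if (!file.exists(sc)) {
    stop("cannot decode video '", path, "': missing ", VIDEO_SIDECAR)
  }
  jsonlite::fromJSON(sc)
}

list_frame_files <- function(path) {
  files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("cannot decode video '", path, "': no PNG frames found")
  }
  files
}

read_frame_png <- function(file) {
  a <- png::readPNG(file)
  if (length(dim(a)) == 3L) {
    # color source: standard luminance conversion
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  round(a * 255)
}

#' Probe a video's metadata
#'
#' @param path Path to an image-sequence video directory.
#' @return List of class `video_meta`: `path`, `fps`, `frame_count`, `height`,
#'   `width` (native, pre-crop).
#' @export
probe_video <- function(path) {
  if (!dir.exists(path)) {
    stop("cannot decode video '", path, "': no such directory")
  }
  meta <- read_sidecar(path)
  files <- list_frame_files(path)
  n_claimed <- meta$frame_count
  if (!is.null(n_claimed) && n_claimed != length(files)) {
    warning(sprintf(
      "video '%s' declares %d frames but %d are decodable; using %d",
      path, n_claimed, length(files), length(files)))
  }
  f1 <- read_frame_png(files[[1]])
  structure(list(path = path, fps = meta$fps, frame_count = length(files),
                 height = nrow(f1), width = ncol(f1)),
            class = "video_meta")
}

#' Open a video as a lazy grayscale frame stream
#'
#' Decodes frames on demand (one frame in memory at a time), converting color
#' sources to grayscale by luminance, restricting to `range`, cropping to
#' `crop`, then spatially downsampling by `downsample_factor`.
#'
#' @param path Path to an image-sequence video directory (8-bit PNG frames
#'   plus a JSON metadata sidecar, as written by [write_video()]).
#' @param crop Optional [crop_region()].
#' @param range Optional [frame_range()].
#' @param downsample_factor Optional positive real spatial scale factor.
#' @return A `frame_stream`.
#' @export
open_video <- function(path, crop = NULL, range = NULL,
                       downsample_factor = NULL) {
  meta <- probe_video(path)
  files <- list_frame_files(path)
  s <- new_frame_stream(function(i) read_frame_png(files[[i + 1L]]),
                        meta$frame_count, meta$height, meta$width, meta$fps,
                        path = path)
  if (!is.null(range)) s <- stream_range(s, range)
  if (!is.null(crop)) s <- stream_crop(s, crop)
  if (!is.null(downsample_factor)) s <- stream_downsample(s, downsample_factor)
  s
}

#' Write frames to a lossless image-sequence video
#'
#' Frames are rounded to 8-bit grayscale PNGs, so integer gray levels round-trip
#' bit-exactly through [open_video()].
#'
#' @param x A `frame_stream`, list of matrices, or 3-D array.
#' @param path Output directory (created if needed).
#' @param fps Frame rate recorded in the metadata sidecar (ignored when `x` is
#'   already a stream).
#' @return `path`, invisibly.
#' @export
write_video <- function(x, path, fps = 30) {
  if (!inherits(x, "frame_stream")) x <- as_frame_stream(x, fps = fps)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- x$meta$frame_count
  for (i in seq_len(n) - 1L) {
    f <- pmin(pmax(round(frame_at(x, i)), 0), 255)
    png::writePNG(f / 255, file.path(path, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(
    list(fps = x$meta$fps, frame_count = n,
         height = x$meta$height, width = x$meta$width),
    file.path(path, VIDEO_SIDECAR), auto_unbox = TRUE)
  invisible(path)
}

is_video_dir <- function(path) {
  dir.exists(path) && file.exists(file.path(path, VIDEO_SIDECAR))
}
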