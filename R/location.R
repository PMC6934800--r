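# Location tracking: reference-frame differencing, percentile thresholding,
# optional prior-position weighting, and center-of-mass localization.

#' Location-tracking parameters
#'
#' @param diff_mode How the frame is compared to the reference:
#'   `"absolute"` uses `|frame - reference|` and tracks regardless of contrast
#'   polarity; `"animal_lighter"` keeps `frame - reference` (clipped at 0);
#'   `"animal_darker"` keeps `reference - frame` (clipped at 0).
#' @param loc_thresh Percentile in (0, 100) of the per-frame pixel differences
#'   below which differences are zeroed. The cutoff scales with the frame's own
#'   difference distribution, so tracking is robust to global illumination
#'   level. Default 99.
#' @param use_window Apply a weighting window around the previous frame's
#'   center of mass (off by default; recommended when objects other than the
#'   animal can enter the field of view, or for small targets in noisy video).
#' @param window_size Side length in pixels of the square window (odd).
#' @param window_weight Weight `omega` in \[0, 1\]: difference values outside
#'   the window are multiplied by `1 - omega`, so `omega = 1` zeroes them and
#'   `omega = 0` disables the window.
#' @param reference_sample_n Number of frames sampled (without replacement)
#'   when building the median reference frame. Default 100.
#' @param rng_seed Seed for the reference-frame sampling, recorded in the
#'   reference's provenance.
#' @param binarize Treat all suprathreshold pixels as equal mass instead of
#'   weighting by their difference values (off by default).
#' @return An object of class `location_params`.
#' @export
location_params <- function(diff_mode = c("absolute", "animal_lighter",
                                          "animal_darker"),
                            loc_thresh = 99, use_window = FALSE,
                            window_size = 61, window_weight = 0.9,
                            reference_sample_n = 100, rng_seed = 1L,
                            binarize = FALSE) {
  diff_mode <- match.arg(diff_mode)
  stopifnot(loc_thresh > 0, loc_thresh < 100,
            window_weight >= 0, window_weight <= 1,
            window_size >= 1, window_size %% 2 == 1,
            reference_sample_n >= 1)
  structure(list(diff_mode = diff_mode, loc_thresh = loc_thresh,
                 use_window = isTRUE(use_window),
                 window_size = as.integer(window_size),
                 window_weight = window_weight,
                 reference_sample_n = as.integer(reference_sample_n),
                 rng_seed = as.integer(rng_seed),
                 binarize = isTRUE(binarize)),
            class = "location_params")
}

#' Build the median reference frame
#'
#' Samples `reference_sample_n` frame indices uniformly without replacement
#' (all frames if the video is shorter) and takes the pixel-wise median across
#' the sampled frames. As long as the animal occupies any given pixel in fewer
#' than half of the sampled frames, the median recovers the empty arena. When
#' that assumption fails (an animal parked in one spot for most of the
#' session), pass an `external_stream` of the empty arena instead; its frames
#' are all used.
#'
#' @param stream `frame_stream` of the session being analyzed.
#' @param params [location_params()]; `reference_sample_n` and `rng_seed` are
#'   used here.
#' @param external_stream Optional `frame_stream` of the arena without the
#'   animal, with identical post-crop dimensions.
#' @return Object of class `reference_frame`: `image` (matrix),
#'   `sample_indices` (0-based), `source`, `rng_seed`.
#' @export
make_reference <- function(stream, params = location_params(),
                           external_stream = NULL) {
  stopifnot(inherits(stream, "frame_stream"))
  src <- stream; source <- "same_video"
  if (!is.null(external_stream)) {
    if (external_stream$meta$height != stream$meta$height ||
        external_stream$meta$width != stream$meta$width) {
      stop("external reference video dimensions do not match the session video")
    }
    src <- external_stream; source <- "external_video"
  }
  n <- src$meta$frame_count
  idx <- if (source == "external_video" || n <= params$reference_sample_n) {
    seq_len(n) - 1L
  } else {
    sort(with_seed(params$rng_seed, sample.int(n, params$reference_sample_n)) - 1L)
  }
  h <- src$meta$height; w <- src$meta$width
  stack <- matrix(0, length(idx), h * w)
  for (k in seq_along(idx)) stack[k, ] <- as.vector(frame_at(src, idx[k]))
  img <- matrix(col_medians(stack), h, w)
  structure(list(image = img, sample_indices = idx, source = source,
                 rng_seed = params$rng_seed),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf("<reference_frame> %dx%d px, median of %d frames (%s)\n",
              nrow(x$image), ncol(x$image), length(x$sample_indices), x$source))
  invisible(x)
}

ref_image <- function(reference) {
  if (inherits(reference, "reference_frame")) reference$image else reference
}

#' Pixel-wise difference between a frame and the reference
#'
#' @param frame Grayscale matrix.
#' @param reference A `reference_frame` or plain matrix of the same size.
#' @param diff_mode `"absolute"`, `"animal_lighter"`, or `"animal_darker"`.
#' @return Non-negative matrix of difference values.
#' @export
frame_difference <- function(frame, reference,
                             diff_mode = c("absolute", "animal_lighter",
                                           "animal_darker")) {
  diff_mode <- match.arg(diff_mode)
  ref <- ref_image(reference)
  if (!identical(dim(frame), dim(ref))) {
    stop("frame and reference dimensions differ")
  }
  switch(diff_mode,
         absolute = abs(frame - ref),
         animal_lighter = pmax(frame - ref, 0),
         animal_darker = pmax(ref - frame, 0))
}

#' Zero all difference values at or below a percentile cutoff
#'
#' The cutoff is the `loc_thresh`-th linear-interpolation percentile of all
#' entries; entries strictly above it keep their values, the rest become 0.
#'
#' @param diff Non-negative matrix of pixel differences.
#' @param loc_thresh Percentile in (0, 100).
#' @return Matrix of the same size.
#' @export
threshold_by_percentile <- function(diff, loc_thresh = 99) {
  stopifnot(loc_thresh > 0, loc_thresh < 100)
  cutoff <- percentile_of(diff, loc_thresh)
  diff[diff <= cutoff] <- 0
  diff
}

#' Down-weight difference values outside a window around the prior position
#'
#' Values inside the `window_size` x `window_size` square centered on the
#' pixel nearest `prior_com` (clipped at the image edges) are unchanged;
#' values outside are multiplied by `1 - window_weight`.
#'
#' @param diff Non-negative difference matrix.
#' @param prior_com Numeric `(x, y)` (0-based) — usually the previous frame's
#'   center of mass.
#' @param window_size Odd square side length in pixels.
#' @param window_weight Weight `omega` in \[0, 1\].
#' @return Matrix of the same size.
#' @export
apply_location_weight <- function(diff, prior_com, window_size = 61,
                                  window_weight = 0.9) {
  stopifnot(window_weight >= 0, window_weight <= 1)
  if (window_weight == 0) return(diff)
  h <- nrow(diff); w <- ncol(diff)
  cx <- round(prior_com[[1]]) + 1L  # to 1-based column
  cy <- round(prior_com[[2]]) + 1L  # to 1-based row
  hw <- (as.integer(window_size) - 1L) %/% 2L
  rows <- max(1L, cy - hw):min(h, cy + hw)
  cols <- max(1L, cx - hw):min(w, cx + hw)
  out <- diff * (1 - window_weight)
  out[rows, cols] <- diff[rows, cols]
  out
}

#' Intensity-weighted center of mass
#'
#' @param weighted_diff Non-negative matrix.
#' @param fallback `(x, y)` returned (with a warning) when the matrix is all
#'   zero — the prior position, or the image center on the first frame.
#' @return Numeric `c(x, y)`, 0-based, sub-pixel.
#' @export
center_of_mass <- function(weighted_diff, fallback = NULL) {
  tot <- sum(weighted_diff)
  if (tot <= 0) {
    if (is.null(fallback)) {
      fallback <- c((ncol(weighted_diff) - 1) / 2, (nrow(weighted_diff) - 1) / 2)
    }
    warning("all-zero difference frame; falling back to prior position")
    return(as.numeric(fallback))
  }
  xs <- colSums(weighted_diff)
  ys <- rowSums(weighted_diff)
  c(sum(xs * (seq_along(xs) - 1)) / tot,
    sum(ys * (seq_along(ys) - 1)) / tot)
}

#' Pixel-to-physical-unit scale calibration
#'
#' Define the scale from any two points a known distance apart in the frame.
#'
#' @param point_a,point_b `(x, y)` pixel coordinates of two distinct points.
#' @param true_distance Real-world distance between them (> 0).
#' @param unit_label Unit name, e.g. `"cm"`.
#' @return Object of class `scale_calibration` with `factor` = units per pixel.
#' @export
calibrate_scale <- function(point_a, point_b, true_distance,
                            unit_label = "cm") {
  d <- sqrt(sum((as.numeric(point_a) - as.numeric(point_b))^2))
  if (d == 0) stop("calibration points must be distinct")
  if (true_distance <= 0) stop("true_distance must be positive")
  structure(list(point_a = as.numeric(point_a), point_b = as.numeric(point_b),
                 true_distance = true_distance, unit_label = unit_label,
                 factor = true_distance / d),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> %.6g %s/px\n", x$factor, x$unit_label))
  invisible(x)
}

#' Polygonal region of interest
#'
#' @param name Unique label.
#' @param x,y Vertex coordinates (>= 3 vertices, simple polygon, 0-based
#'   pixels).
#' @return Object of class `roi`.
#' @export
roi_polygon <- function(name, x, y) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(x) == length(y), length(x) >= 3L)
  # shoelace area; zero means degenerate
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  area <- abs(sum(x * y2 - x2 * y)) / 2
  if (area <= 0) stop("degenerate ROI polygon '", name, "' (zero area)")
  structure(list(name = name, x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param point `(x, y)` coordinates.
#' @param roi An [roi_polygon()].
#' @return `TRUE` if the point is inside or on the boundary.
#' @export
point_in_roi <- function(point, roi) {
  stopifnot(inherits(roi, "roi"))
  px <- point[[1]]; py <- point[[2]]
  xs <- roi$x; ys <- roi$y
  n <- length(xs)
  j <- n
  inside <- FALSE
  eps <- 1e-9
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment check
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) ((px - xi) * dx + (py - yi) * dy) / len2 else 0
    t <- min(max(t, 0), 1)
    if ((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2 <= eps^2) return(TRUE)
    # even-odd ray crossing
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * dx / dy
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# single-frame localization; diff pipeline shared by track_session
locate_frame <- function(frame, ref, params, prior_com, fallback) {
  d <- frame_difference(frame, ref, params$diff_mode)
  if (params$use_window && !is.null(prior_com)) {
    d <- apply_location_weight(d, prior_com, params$window_size,
                               params$window_weight)
  }
  d <- threshold_by_percentile(d, params$loc_thresh)
  if (params$binarize) d <- (d > 0) * 1
  center_of_mass(d, fallback)
}

#' Track the animal's center of mass across a session
#'
#' Per frame: difference against the reference, optionally down-weight pixels
#' outside a window around the previous position, zero everything at or below
#' the percentile cutoff of the (weighted) difference image, and take the
#' intensity-weighted center of mass of what survives. Euclidean step
#' distances, optional physical-unit conversion and per-ROI occupancy flags
#' are tabulated alongside.
#'
#' @param stream `frame_stream` of the session.
#' @param reference A `reference_frame` from [make_reference()]; built
#'   automatically from the stream when `NULL`.
#' @param params [location_params()].
#' @param rois List of [roi_polygon()] objects (names must be unique).
#' @param calibration Optional [calibrate_scale()] result.
#' @param file Label written to the `file` column of the result.
#' @return A `tracking_result` data frame with one row per frame: `file`,
#'   `frame` (original video index), `x`, `y`, `distance_px`, optionally
#'   `distance_<unit>`, and one 0/1 column per ROI. The reference and
#'   parameters are attached as attributes.
#' @export
track_session <- function(stream, reference = NULL,
                          params = location_params(), rois = list(),
                          calibration = NULL, file = NA_character_) {
  stopifnot(inherits(stream, "frame_stream"))
  if (is.null(reference)) reference <- make_reference(stream, params)
  ref <- ref_image(reference)
  if (nrow(ref) != stream$meta$height || ncol(ref) != stream$meta$width) {
    stop("reference dimensions do not match the stream")
  }
  roi_names <- vapply(rois, function(r) r$name, character(1))
  if (anyDuplicated(roi_names)) stop("ROI names must be unique")
  n <- stream$meta$frame_count
  x <- y <- numeric(n)
  prior <- NULL
  center <- c((ncol(ref) - 1) / 2, (nrow(ref) - 1) / 2)
  for (t in seq_len(n)) {
    fallback <- if (is.null(prior)) center else prior
    p <- locate_frame(frame_at(stream, t - 1L), ref, params, prior, fallback)
    x[t] <- p[1]; y[t] <- p[2]
    prior <- p
  }
  dist_px <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  out <- data.frame(
    file = if (is.na(file) && !is.na(stream$meta$path))
      basename(stream$meta$path) else file,
    frame = stream$meta$first_frame + seq_len(n) - 1L,
    x = x, y = y, distance_px = dist_px,
    stringsAsFactors = FALSE)
  if (!is.null(calibration)) {
    out[[paste0("distance_", calibration$unit_label)]] <-
      dist_px * calibration$factor
  }
  for (r in rois) {
    out[[r$name]] <- vapply(seq_len(n), function(t)
      as.integer(point_in_roi(c(x[t], y[t]), r)), integer(1))
  }
  structure(out, class = c("tracking_result", "data.frame"),
            params = params, reference = reference, calibration = calibration,
            rois = rois, fps = stream$meta$fps)
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d frames, total distance %.2f px\n",
              nrow(x), sum(x$distance_px)))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.tracking_result <- function(object, ...) {
  rois <- attr(object, "rois")
  cal <- attr(object, "calibration")
  out <- list(n_frames = nrow(object),
              total_distance_px = sum(object$distance_px))
  if (!is.null(cal)) {
    out[[paste0("total_distance_", cal$unit_label)]] <-
      sum(object$distance_px) * cal$factor
  }
  for (r in rois) {
    out[[paste0("prop_", r$name)]] <- mean(object[[r$name]])
  }
  structure(out, class = "summary.tracking_result")
}

#' @export
print.summary.tracking_result <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%s: %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Occupancy heatmap from a tracking result
#'
#' Counts of per-frame positions on the pixel grid (optionally binned);
#' total count equals the number of analyzed frames.
#'
#' @param result A `tracking_result`.
#' @param bin_px Side length in pixels of each heatmap cell.
#' @return Integer matrix of counts (rows = y bins, columns = x bins).
#' @export
occupancy_heatmap <- function(result, bin_px = 1) {
  stopifnot(inherits(result, "tracking_result"), bin_px >= 1)
  ref <- ref_image(attr(result, "reference"))
  h <- ceiling(nrow(ref) / bin_px); w <- ceiling(ncol(ref) / bin_px)
  m <- matrix(0L, h, w)
  ix <- pmin(pmax(floor(result$x / bin_px), 0), w - 1) + 1
  iy <- pmin(pmax(floor(result$y / bin_px), 0), h - 1) + 1
  for (t in seq_along(ix)) m[iy[t], ix[t]] <- m[iy[t], ix[t]] + 1L
  m
}
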