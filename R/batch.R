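# Batch processing: run one pipeline over every video in a folder with
# identical parameters, writing frame-by-frame CSVs, a combined summary, and
# a batch log. A failure on one video is logged and does not abort the rest.

#' Batch configuration
#'
#' @param input_dir Folder containing videos (image-sequence directories).
#' @param out_dir Output folder for CSVs, plots and the batch log.
#' @param pattern Optional glob filter on video names (e.g. `"mouse*"`).
#' @param crop Optional [crop_region()] applied to every video.
#' @param range Optional [frame_range()] applied to every video.
#' @param downsample_factor Optional spatial scale factor.
#' @param bins Optional [bin_spec()], or a number of seconds to tile each
#'   session with [bins_by_seconds()].
#' @return Object of class `batch_config`.
#' @export
batch_config <- function(input_dir, out_dir, pattern = NULL, crop = NULL,
                         range = NULL, downsample_factor = NULL, bins = NULL) {
  if (!dir.exists(input_dir)) stop("input folder does not exist: ", input_dir)
  structure(list(input_dir = input_dir, out_dir = out_dir, pattern = pattern,
                 crop = crop, range = range,
                 downsample_factor = downsample_factor, bins = bins),
            class = "batch_config")
}

list_batch_videos <- function(config) {
  cand <- list.dirs(config$input_dir, recursive = FALSE)
  cand <- cand[vapply(cand, is_video_dir, TRUE)]
  if (!is.null(config$pattern)) {
    cand <- cand[grepl(utils::glob2rx(config$pattern), basename(cand))]
  }
  sort(cand)
}

resolve_bins <- function(bins, result) {
  if (is.null(bins)) {
    return(bin_spec("session", min(result$frame), max(result$frame) + 1L))
  }
  if (is.numeric(bins)) {
    return(bins_by_seconds(bins, attr(result, "fps"), nrow(result),
                           min(result$frame)))
  }
  bins
}

#' Process every video in a folder
#'
#' Runs the location-tracking or freezing pipeline on each video with
#' identical parameters (the reference frame is always generated from each
#' video itself), writes one frame-by-frame CSV per video plus a combined
#' `summary.csv`, and logs successes and failures to `batch_log.txt`.
#' Outputs are deterministic given the parameter seed.
#'
#' @param config A [batch_config()].
#' @param pipeline `"location"` or `"freeze"`.
#' @param params [location_params()] (location pipeline).
#' @param rois List of [roi_polygon()] (location pipeline).
#' @param calibration Optional [calibrate_scale()] result (location pipeline).
#' @param mt,ft,min_duration_sec,sigma Freezing-pipeline parameters.
#' @param plots Also write summary plots per video.
#' @return Invisibly, a list with `outputs` (per-video CSV paths), `summary`
#'   (summary CSV path), `log` (log path) and `failures` (named character
#'   vector of error messages, empty when everything succeeded).
#' @export
run_batch <- function(config, pipeline = c("location", "freeze"),
                      params = location_params(), rois = list(),
                      calibration = NULL,
                      mt = NULL, ft = NULL, min_duration_sec = 0.5, sigma = 1,
                      plots = FALSE) {
  pipeline <- match.arg(pipeline)
  stopifnot(inherits(config, "batch_config"))
  if (pipeline == "freeze" && (is.null(mt) || is.null(ft))) {
    stop("the freeze pipeline needs mt and ft")
  }
  videos <- list_batch_videos(config)
  if (length(videos) == 0L) {
    stop("no videos matched in ", config$input_dir)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "batch_log.txt")
  log_lines <- character(0)
  outputs <- character(0)
  failures <- character(0)
  summaries <- list()
  for (v in videos) {
    name <- basename(v)
    res <- tryCatch({
      s <- open_video(v, crop = config$crop, range = config$range,
                      downsample_factor = config$downsample_factor)
      if (pipeline == "location") {
        r <- track_session(s, reference = NULL, params = params, rois = rois,
                           calibration = calibration)
        out <- file.path(config$out_dir, paste0(name, "_tracking.csv"))
      } else {
        r <- freeze_session(s, mt = mt, ft = ft,
                            min_duration_sec = min_duration_sec, sigma = sigma)
        out <- file.path(config$out_dir, paste0(name, "_freeze.csv"))
      }
      write_result_csv(r, out)
      if (plots) make_plots(r, config$out_dir, prefix = name)
      summaries[[name]] <- summarize_bins(r, resolve_bins(config$bins, r))
      outputs <- c(outputs, out)
      log_lines <- c(log_lines, paste0("ok: ", name))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      failures[name] <- res
      log_lines <- c(log_lines, paste0("FAILED: ", name, " -- ", res))
    }
  }
  summary_path <- NA_character_
  if (length(summaries) > 0) {
    summary_path <- file.path(config$out_dir, "summary.csv")
    write_result_csv(do.call(rbind, unname(summaries)), summary_path)
  }
  writeLines(log_lines, log_path)
  if (length(failures) > 0) {
    warning(sprintf("%d of %d videos failed; see %s",
                    length(failures), length(videos), log_path))
  }
  invisible(list(outputs = outputs, summary = summary_path, log = log_path,
                 failures = failures))
}
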