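# End-to-end orchestration: band extraction -> ROI crop -> binarize ->
# opening -> size filter -> boundary tracing -> morphometry -> per-frame
# summary -> time-series analysis.

#' Process one frame through the full pipeline
#'
#' @param frame A `drop_frame`.
#' @param config A [pipeline_config()].
#' @return A [summarize_frame()] result; the per-droplet table carries
#'   centroids in full-frame coordinates (ROI offset added back).
#' @export
process_frame <- function(frame, config = pipeline_config()) {
  band <- extract_band(frame, config$band)
  off <- c(0L, 0L)
  if (!is.null(config$roi)) {
    band <- crop_roi(band, config$roi)
    off <- attr(band, "roi_offset")
  }
  mask <- binarize(band, config$thr, config$polarity)
  if (config$se_size > 1) mask <- opening(mask, struct_elem(config$se_size))
  mask <- remove_small_objects(mask, config$min_area)
  boundaries <- find_all_boundaries(mask)
  calib <- calibrate_from_channel(config$channel_width_px,
                                  config$channel_width_mm)
  measures <- do.call(rbind, lapply(boundaries, measure_droplet,
                                    mask = mask, calibration = calib,
                                    perimeter_method = config$perimeter_method))
  if (!is.null(measures) && nrow(measures) > 0) {
    measures$centroid_row <- measures$centroid_row + off[1]
    measures$centroid_col <- measures$centroid_col + off[2]
  }
  summarize_frame(measures, frame_id = frame$frame_id,
                  timestamp = frame$timestamp)
}

#' Run a full droplet-measurement experiment over a frame directory
#'
#' Reads every PNG/TIFF frame in `frame_dir` (sorted by name, timestamps
#' parsed from the trailing number of the file name), processes each
#' through the pipeline, and writes `droplets.csv` (one row per droplet),
#' `frames.csv` (one row per frame) and `trend.json` (quadratic fit of
#' mean diameter vs time, when at least 3 frames have defined means) to
#' `out_dir`. Deterministic: identical inputs and config give identical
#' output bytes. Unreadable frames are skipped with a warning and counted
#' in the returned summary.
#'
#' @param frame_dir Directory of frames.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a list: `frames` (data frame), `droplets` (data
#'   frame), `trend` (`trend_fit` or `NULL`), `n_failed`.
#' @export
run_experiment <- function(frame_dir, config = pipeline_config(),
                           out_dir = NULL) {
  paths <- sort(list.files(frame_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0) stop("no frames found in ", frame_dir)
  summaries <- list()
  droplets <- list()
  n_failed <- 0L
  for (p in paths) {
    frame <- tryCatch(read_frame(p), error = function(e) e)
    if (inherits(frame, "error")) {
      warning("skipping unreadable frame ", basename(p), ": ",
              conditionMessage(frame))
      n_failed <- n_failed + 1L
      next
    }
    s <- process_frame(frame, config)
    message(sprintf("%s: t = %s s, %d droplet(s)", s$frame_id,
                    format(s$timestamp), s$droplet_count))
    summaries[[length(summaries) + 1L]] <- s
    if (!is.null(s$droplets) && nrow(s$droplets) > 0) {
      droplets[[length(droplets) + 1L]] <-
        cbind(frame_id = s$frame_id, t_s = s$timestamp, s$droplets)
    }
  }
  frames_df <- summaries_to_df(summaries)
  droplets_df <- if (length(droplets) > 0) do.call(rbind, droplets) else
    data.frame()
  trend <- NULL
  if (sum(is.finite(frames_df$mean_diameter_mm)) >= 3) {
    trend <- fit_diameter_trend(summaries)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(droplets_df, file.path(out_dir, "droplets.csv"),
                     row.names = FALSE)
    utils::write.csv(frames_df, file.path(out_dir, "frames.csv"),
                     row.names = FALSE)
    if (!is.null(trend)) {
      cf <- as.list(coef(trend))
      jsonlite::write_json(
        c(cf, list(rmse = trend$rmse, r2 = trend$r_squared,
                   n = trend$n_points)),
        file.path(out_dir, "trend.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(list(frames = frames_df, droplets = droplets_df, trend = trend,
                 n_failed = n_failed))
}

#' Default ROI covering the channel band of a synthetic scene
#'
#' Convenience for analysing rendered scenes: the inclusive row range of
#' the channel interior across the full image width.
#'
#' @param spec A [scene_spec()].
#' @return `c(r0, c0, r1, c1)` for [crop_roi()].
#' @export
channel_roi <- function(spec) {
  ch <- channel_rows(spec)
  c(min(ch), 1L, max(ch), spec$image_width)
}
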