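# Raster and config I/O. PNG and TIFF rasters are normalized to [0, 1]
# doubles on read (8- and 16-bit files come back already scaled from the
# readers); greyscale and alpha layouts are promoted to plain RGB.

#' Read an image file as a frame
#'
#' @param path PNG or TIFF file.
#' @param timestamp Acquisition time in seconds; by default parsed from a
#'   `frame_{t}` file-name pattern, else `NA`.
#' @return A [new_frame()] object.
#' @export
read_frame <- function(path, timestamp = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3) stop("expected an RGB(A) or greyscale raster")
  px <- pmin(pmax(px, 0), 1)
  id <- tools::file_path_sans_ext(basename(path))
  if (is.null(timestamp)) {
    m <- regmatches(id, regexpr("[0-9]+$", id))
    timestamp <- if (length(m) == 1) as.numeric(m) else NA_real_
  }
  new_frame(px, timestamp = timestamp, frame_id = id)
}

#' Write a frame to a PNG file
#'
#' @param frame A `drop_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame$pixels, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the still-image pipeline. Defaults are the
#' operating point used throughout: red band, threshold 0.7 with droplets
#' darker than oil (`foreground_lt`), one opening with a 3 x 3 square,
#' minimum object area 25 px, and calibration from a 6 mm channel
#' spanning 102.768 px (17.128 px/mm).
#'
#' @param band Colour band to analyse.
#' @param thr Binarization threshold in \[0, 1\].
#' @param polarity `"foreground_lt"` or `"foreground_ge"`.
#' @param se_size Structuring-element side (odd; 1 disables opening's
#'   effect).
#' @param min_area Minimum droplet area in px.
#' @param roi `c(r0, c0, r1, c1)` inclusive bounds, or `NULL` for the
#'   full frame.
#' @param channel_width_mm,channel_width_px Calibration inputs.
#' @param perimeter_method Passed to [perimeter_px()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = "red", thr = 0.7,
                            polarity = "foreground_lt",
                            se_size = 3, min_area = 25, roi = NULL,
                            channel_width_mm = 6,
                            channel_width_px = 102.768,
                            perimeter_method = "chain_weighted") {
  structure(list(band = band, thr = thr, polarity = polarity,
                 se_size = as.integer(se_size), min_area = min_area,
                 roi = roi, channel_width_mm = channel_width_mm,
                 channel_width_px = channel_width_px,
                 perimeter_method = perimeter_method),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognized keys match the [pipeline_config()] arguments; missing keys
#' keep their defaults, unknown keys are an error.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext)
  )
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$roi)) vals$roi <- as.integer(unlist(vals$roi))
  do.call(pipeline_config, vals)
}
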