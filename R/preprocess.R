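#' Construct a frame object
#'
#' A frame is an RGB raster with intensities in \[0, 1\] plus acquisition
#' metadata. Rasters read from 8-bit or 16-bit files are normalized to
#' \[0, 1\] on read (see [read_frame()]).
#'
#' @param pixels Numeric `M x N x 3` array, values in \[0, 1\].
#' @param timestamp Acquisition time in seconds.
#' @param frame_id Identifier string.
#' @return A `drop_frame` object.
#' @export
new_frame <- function(pixels, timestamp = NA_real_, frame_id = "frame") {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("pixels must be an M x N x 3 array")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]")
  }
  structure(
    list(pixels = pixels, timestamp = as.numeric(timestamp),
         frame_id = as.character(frame_id)),
    class = "drop_frame"
  )
}

#' @export
print.drop_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<drop_frame %s> %d x %d RGB, t = %s s\n",
              x$frame_id, d[1], d[2], format(x$timestamp)))
  invisible(x)
}

#' Extract a colour band from an RGB frame
#'
#' Returns one colour plane of the frame unchanged. The red band is the
#' usual choice for water-in-oil droplets: oil transmits strongly in red
#' while dyed water absorbs it, so the red plane shows the largest
#' droplet/background contrast.
#'
#' @param frame A `drop_frame` or a bare `M x N x 3` array.
#' @param band One of `"red"`, `"green"`, `"blue"`.
#' @return Numeric `M x N` matrix in \[0, 1\] with attributes `band` and
#'   `frame_id`.
#' @export
extract_band <- function(frame, band = c("red", "green", "blue")) {
  band <- match.arg(band)
  px <- if (inherits(frame, "drop_frame")) frame$pixels else frame
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop("frame must carry an M x N x 3 raster")
  }
  k <- match(band, c("red", "green", "blue"))
  out <- px[, , k]
  attr(out, "band") <- band
  attr(out, "frame_id") <-
    if (inherits(frame, "drop_frame")) frame$frame_id else NA_character_
  out
}

#' Histogram of a band image
#'
#' @param band_image Numeric matrix in \[0, 1\].
#' @param bins Number of equal-width bins over \[0, 1\] (>= 2).
#' @return Data frame with `mid` (bin midpoint) and `count`; counts sum to
#'   the pixel count.
#' @export
band_histogram <- function(band_image, bins = 64) {
  if (bins < 2) stop("bins must be >= 2")
  breaks <- seq(0, 1, length.out = bins + 1)
  h <- hist(as.numeric(band_image), breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Binarize a band image at a fixed threshold
#'
#' Maps a \[0, 1\] band image to a logical droplet mask. With polarity
#' `"foreground_ge"` a pixel is foreground iff its value is `>= thr`
#' (values exactly at the threshold are foreground). Dyed-water droplets
#' are darker than the oil background in the red band, so the pipeline
#' default polarity is `"foreground_lt"`: foreground iff value `< thr`.
#'
#' @param band_image Numeric matrix in \[0, 1\].
#' @param thr Threshold in \[0, 1\] (experiment-selected default 0.7).
#' @param polarity `"foreground_lt"` (default) or `"foreground_ge"`.
#' @return Logical matrix, `TRUE` = droplet.
#' @examples
#' binarize(matrix(c(0.2, 0.7, 0.9), 1), thr = 0.7, polarity = "foreground_ge")
#' @export
binarize <- function(band_image, thr = 0.7,
                     polarity = c("foreground_lt", "foreground_ge")) {
  polarity <- match.arg(polarity)
  if (thr < 0 || thr > 1) stop("thr must lie in [0, 1]")
  v <- as.matrix(band_image)
  out <- if (polarity == "foreground_ge") v >= thr else v < thr
  attributes(out) <- list(dim = dim(v))
  out
}

#' Crop a region of interest
#'
#' Returns the sub-raster covering the outlet-channel segment under
#' analysis and records the offset so ROI coordinates map back to the
#' original frame: original = ROI coordinate + `attr(x, "roi_offset")`.
#'
#' @param a Matrix or `M x N x 3` array.
#' @param roi Integer vector `c(r0, c0, r1, c1)`, 1-based inclusive bounds.
#' @return The cropped object with attribute `roi_offset = c(r0 - 1, c0 - 1)`.
#' @export
crop_roi <- function(a, roi) {
  d <- dim(a)
  roi <- as.integer(roi)
  if (length(roi) != 4) stop("roi must be c(r0, c0, r1, c1)")
  if (roi[1] < 1 || roi[2] < 1 || roi[3] > d[1] || roi[4] > d[2] ||
      roi[1] > roi[3] || roi[2] > roi[4]) {
    stop("roi outside image bounds")
  }
  out <- if (length(d) == 3) {
    a[roi[1]:roi[3], roi[2]:roi[4], , drop = FALSE]
  } else {
    a[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  }
  attr(out, "roi_offset") <- c(roi[1] - 1L, roi[2] - 1L)
  out
}
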