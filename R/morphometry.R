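# Droplet morphometry: area, perimeter, radii, calibrated diameter.
#
# Two radius estimates target the same circle: one from the filled pixel
# area (r = sqrt(A / pi)) and one from the contour perimeter
# (r = P / 2 pi). Their mean gives the reported diameter, which is then
# converted to millimetres with a pixel-per-millimetre ratio calibrated
# against the known outlet-channel width.

# flood-fill the 8-connected component of `mask` containing `start`;
# returns an n x 2 matrix of (row, col)
component_pixels <- function(mask, start) {
  nr <- nrow(mask)
  idx <- flood_fill(mask, (start[2] - 1L) * nr + start[1])
  cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
}

#' Area of a traced droplet in pixels
#'
#' Counts the foreground pixels of the filled component the boundary was
#' traced from (contour plus interior), i.e. the number of white pixels
#' belonging to that droplet.
#'
#' @param boundary A `drop_boundary` from [trace_boundary()].
#' @param mask The logical mask the boundary was traced from.
#' @return Pixel count (numeric).
#' @export
area_px <- function(boundary, mask) {
  nrow(component_pixels(mask, boundary$pixels[1L, ]))
}

#' Perimeter of a traced droplet in pixels
#'
#' `"chain_weighted"` (default) measures the cyclic contour path length
#' with weight 1 per axial step and sqrt(2) per diagonal step, the
#' standard chain-code length; `"pixel_count"` counts distinct contour
#' pixels, the strictest reading of a perimeter "obtained in pixels".
#' A single-pixel boundary has chain-weighted perimeter 0 and pixel count
#' 1.
#'
#' @param boundary A `drop_boundary`.
#' @param method `"chain_weighted"` or `"pixel_count"`.
#' @return Perimeter in pixels (numeric).
#' @export
perimeter_px <- function(boundary, method = c("chain_weighted", "pixel_count")) {
  method <- match.arg(method)
  px <- boundary$pixels
  n <- nrow(px)
  if (method == "pixel_count") return(nrow(unique(px)))
  if (n == 1L) return(0)
  nxt <- px[c(2:n, 1L), , drop = FALSE]
  diag_step <- (nxt[, 1] != px[, 1]) & (nxt[, 2] != px[, 2])
  sum(ifelse(diag_step, sqrt(2), 1))
}

#' Pixel-to-millimetre calibration from the outlet channel width
#'
#' The outlet channel width is a known device parameter (6 mm); measuring
#' its apparent width in pixels fixes the scale of the whole image.
#'
#' @param channel_width_px Measured channel width in pixels (> 0).
#' @param channel_width_mm Known channel width in mm (> 0, default 6).
#' @return A `calibration` object with `px_per_mm =
#'   channel_width_px / channel_width_mm`.
#' @examples
#' calibrate_from_channel(102.768, 6)  # 17.128 px/mm
#' @export
calibrate_from_channel <- function(channel_width_px, channel_width_mm = 6) {
  if (channel_width_px <= 0 || channel_width_mm <= 0) {
    stop("channel widths must be strictly positive")
  }
  structure(
    list(channel_width_mm = channel_width_mm,
         channel_width_px = channel_width_px,
         px_per_mm = channel_width_px / channel_width_mm),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g mm channel = %g px; %g px/mm\n",
              x$channel_width_mm, x$channel_width_px, x$px_per_mm))
  invisible(x)
}

#' Estimate the channel width in pixels from a channel mask
#'
#' Helper for calibration when no external measurement is available:
#' returns the median vertical extent (pixels per column) of a logical
#' mask marking the channel interior. The default calibration path takes
#' a measured `channel_width_px` instead.
#'
#' @param channel_mask Logical matrix, `TRUE` inside the channel.
#' @return Median column height in pixels.
#' @export
estimate_channel_width_px <- function(channel_mask) {
  check_mask(channel_mask)
  heights <- colSums(channel_mask)
  stats::median(heights[heights > 0])
}

#' Measure one traced droplet
#'
#' Computes the area- and perimeter-based radii, their mean, and the
#' calibrated diameter, and flags droplets whose contour touches the edge
#' of the analysed region (such partial droplets are excluded from frame
#' means).
#'
#' @param boundary A `drop_boundary`.
#' @param mask The mask the boundary was traced from (defines the region
#'   edges for the border flag).
#' @param calibration A `calibration` object.
#' @param perimeter_method Passed to [perimeter_px()].
#' @return One-row data frame: `component_id`, `area_px2`, `perimeter_px`,
#'   `r_area_px`, `r_perim_px`, `r_avg_px`, `diameter_px`, `diameter_mm`,
#'   `centroid_row`, `centroid_col`, `touches_border`.
#' @export
measure_droplet <- function(boundary, mask, calibration,
                            perimeter_method = "chain_weighted") {
  if (!inherits(calibration, "calibration")) stop("calibration must come from calibrate_from_channel()")
  if (nrow(boundary$pixels) < 1) stop("degenerate boundary")
  comp <- component_pixels(mask, boundary$pixels[1L, ])
  area <- nrow(comp)
  per <- perimeter_px(boundary, perimeter_method)
  r_area <- sqrt(area / pi)
  r_perim <- per / (2 * pi)
  r_avg <- (r_area + r_perim) / 2
  d_px <- 2 * r_avg
  bp <- boundary$pixels
  touches <- any(bp[, 1] == 1L | bp[, 1] == nrow(mask) |
                 bp[, 2] == 1L | bp[, 2] == ncol(mask))
  data.frame(
    component_id = boundary$component_id,
    area_px2 = area,
    perimeter_px = per,
    r_area_px = r_area,
    r_perim_px = r_perim,
    r_avg_px = r_avg,
    diameter_px = d_px,
    diameter_mm = d_px / calibration$px_per_mm,
    centroid_row = mean(comp[, 1]),
    centroid_col = mean(comp[, 2]),
    touches_border = touches
  )
}

#' Summarize the droplets of one frame
#'
#' Averages the calibrated diameters of the whole (non-border-touching)
#' droplets in a frame. A frame with no whole droplet gets count 0 and a
#' missing (`NA`) mean, never 0.
#'
#' @param measures Data frame of per-droplet rows from [measure_droplet()]
#'   (zero rows allowed).
#' @param frame_id Frame identifier.
#' @param timestamp Acquisition time in seconds.
#' @return A `frame_summary`: list with `frame_id`, `timestamp`,
#'   `droplet_count` (whole droplets), `mean_diameter_px`,
#'   `mean_diameter_mm`, and `droplets` (the full per-droplet table).
#' @export
summarize_frame <- function(measures, frame_id = "frame", timestamp = NA_real_) {
  if (is.null(measures) || nrow(measures) == 0) {
    keep <- measures
  } else {
    keep <- measures[!measures$touches_border, , drop = FALSE]
  }
  n <- if (is.null(keep)) 0L else nrow(keep)
  structure(
    list(frame_id = frame_id,
         timestamp = as.numeric(timestamp),
         droplet_count = n,
         mean_diameter_px = if (n > 0) mean(keep$diameter_px) else NA_real_,
         mean_diameter_mm = if (n > 0) mean(keep$diameter_mm) else NA_real_,
         droplets = measures),
    class = "frame_summary"
  )
}

#' @export
print.frame_summary <- function(x, ...) {
  cat(sprintf("<frame_summary %s> t = %s s, %d droplet(s), mean diameter %s mm\n",
              x$frame_id, format(x$timestamp), x$droplet_count,
              if (is.na(x$mean_diameter_mm)) "NA"
              else sprintf("%.3f", x$mean_diameter_mm)))
  invisible(x)
}
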