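# Ground-truthed synthetic scenes: a horizontal outlet channel of known
# width imaged top-down, with circular dyed-water droplets advected
# through coconut oil. The renderer is deliberately anti-aliasing-free
# (a pixel belongs to a droplet iff its centre lies inside the disk) so
# digitized areas and boundaries have exact brute-force oracles.

# run code under a temporary seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

frame_seed <- function(seed, t) {
  (as.integer(seed) + 7919 * as.integer(round(t * 100))) %% 2147483629L
}

#' Specify a synthetic droplet scene
#'
#' Defines the geometry, optics and stochastic nuisances of a synthetic
#' outlet-channel image sequence. Geometry defaults reproduce the study
#' conditions: a 640 x 480 raster at 17.128 px/mm with a 6 mm channel
#' (about 103 px tall), and a mean droplet diameter that decays
#' quadratically from 4.04 mm at t = 15 s to 3.05 mm at t = 225 s. Noise
#' sources (specks, pixel noise, brightness drift) default to zero so the
#' clean scene is the baseline; tests and experiments switch them on
#' explicitly.
#'
#' @param image_width,image_height Raster size in px.
#' @param px_per_mm Pixel pitch (px per mm).
#' @param channel_width_mm Known outlet-channel width in mm.
#' @param channel_axis_row Row of the channel centreline (px).
#' @param oil_rgb,droplet_rgb,wall_rgb Colours in \[0, 1\]^3 for the oil
#'   background inside the channel, the dyed-water droplets, and the
#'   region outside the channel. Oil must exceed the droplet colour by at
#'   least 0.2 in the red band so a mid threshold separates them.
#' @param diameter_trend `c(a0, a1, a2)`: mean droplet diameter in mm at
#'   time t seconds is `a0 + a1 t + a2 t^2`.
#' @param diameter_jitter_sd Per-droplet diameter jitter sd in mm.
#' @param droplet_spacing_mm Centre-to-centre droplet spacing in mm; must
#'   exceed the largest generated diameter so droplets never overlap.
#' @param spacing_drift_mm_per_s Linear drift of the spacing with time
#'   (mm/s); a positive drift thins the droplet train, emulating a
#'   falling generation frequency.
#' @param speck_density Expected specks per kilopixel (debris that
#'   thresholds like a droplet but is far smaller).
#' @param speck_max_area Largest speck area in px.
#' @param pixel_noise_sd Additive Gaussian pixel noise sd in \[0, 1\] grey
#'   units (applied per channel, clipped).
#' @param brightness_drift_per_s Global additive brightness offset per
#'   second (\[0, 1\] grey units/s), emulating slow ambient-light drift.
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A validated `scene_spec` list.
#' @export
scene_spec <- function(image_width = 640,
                       image_height = 480,
                       px_per_mm = 17.128,
                       channel_width_mm = 6,
                       channel_axis_row = 240,
                       oil_rgb = c(0.90, 0.60, 0.35),
                       droplet_rgb = c(0.45, 0.30, 0.60),
                       wall_rgb = c(0.15, 0.15, 0.18),
                       diameter_trend = c(4.1410893, -0.0068742857, 9e-6),
                       diameter_jitter_sd = 0.05,
                       droplet_spacing_mm = 6,
                       spacing_drift_mm_per_s = 0,
                       speck_density = 0,
                       speck_max_area = 6,
                       pixel_noise_sd = 0,
                       brightness_drift_per_s = 0,
                       seed = 1L) {
  spec <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    px_per_mm = px_per_mm,
    channel_width_mm = channel_width_mm,
    channel_axis_row = channel_axis_row,
    oil_rgb = oil_rgb, droplet_rgb = droplet_rgb, wall_rgb = wall_rgb,
    diameter_trend = diameter_trend,
    diameter_jitter_sd = diameter_jitter_sd,
    droplet_spacing_mm = droplet_spacing_mm,
    spacing_drift_mm_per_s = spacing_drift_mm_per_s,
    speck_density = speck_density,
    speck_max_area = as.integer(speck_max_area),
    pixel_noise_sd = pixel_noise_sd,
    brightness_drift_per_s = brightness_drift_per_s,
    seed = as.integer(seed)
  )
  if (spec$channel_width_mm * spec$px_per_mm > spec$image_height) {
    stop("channel does not fit in the image height")
  }
  if (spec$oil_rgb[1] - spec$droplet_rgb[1] < 0.2) {
    stop("oil and droplet red-band values must differ by at least 0.2")
  }
  cols <- c(spec$oil_rgb, spec$droplet_rgb, spec$wall_rgb)
  if (any(cols < 0 | cols > 1)) stop("colours must lie in [0, 1]")
  d_hi <- max(trend_diameter(spec, seq(0, 450, by = 5)))
  if (spec$droplet_spacing_mm <= d_hi) {
    stop("droplet_spacing_mm must exceed the largest trend diameter")
  }
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<scene_spec> %d x %d px, %.3f px/mm, %g mm channel\n",
    "  diameter trend: %.4g %+.4g t %+.4g t^2 (mm), jitter sd %g mm\n",
    "  noise: specks %g/kpx, pixel sd %g, drift %g/s; seed %d\n"),
    x$image_width, x$image_height, x$px_per_mm, x$channel_width_mm,
    x$diameter_trend[1], x$diameter_trend[2], x$diameter_trend[3],
    x$diameter_jitter_sd, x$speck_density, x$pixel_noise_sd,
    x$brightness_drift_per_s, x$seed))
  invisible(x)
}

#' Mean droplet diameter of a scene at time t
#'
#' @param spec A `scene_spec`.
#' @param t Time(s) in seconds.
#' @return Mean diameter(s) in mm from the quadratic trend.
#' @export
trend_diameter <- function(spec, t) {
  a <- spec$diameter_trend
  a[1] + a[2] * t + a[3] * t^2
}

# channel band rows: |r - axis| <= half width in px
channel_rows <- function(spec) {
  half <- spec$channel_width_mm * spec$px_per_mm / 2
  r <- seq_len(spec$image_height)
  r[abs(r - spec$channel_axis_row) <= half]
}

# draw the droplet layout for one frame; caller controls the RNG state.
# Diameters are clamped so droplets always fit inside the channel and
# never touch their neighbours.
draw_layout <- function(spec, t) {
  d_mean <- trend_diameter(spec, t)
  spacing <- spec$droplet_spacing_mm + spec$spacing_drift_mm_per_s * t
  width_mm <- spec$image_width / spec$px_per_mm
  phase <- stats::runif(1, 0, spacing)
  centers_mm <- seq(phase, width_mm, by = spacing)
  n <- length(centers_mm)
  if (n == 0) {
    return(data.frame(droplet_id = integer(0), center_row = numeric(0),
                      center_col = numeric(0), diameter_mm = numeric(0),
                      diameter_px = numeric(0)))
  }
  d <- stats::rnorm(n, d_mean, spec$diameter_jitter_sd)
  d <- pmin(pmax(d, 0.2), 0.98 * min(spec$channel_width_mm, spacing))
  col_px <- centers_mm * spec$px_per_mm
  rad_px <- d * spec$px_per_mm / 2
  keep <- (col_px - rad_px >= 1) & (col_px + rad_px <= spec$image_width)
  d <- d[keep]
  col_px <- col_px[keep]
  data.frame(
    droplet_id = seq_along(d),
    center_row = rep(spec$channel_axis_row, length(d)),
    center_col = col_px,
    diameter_mm = d,
    diameter_px = d * spec$px_per_mm
  )
}

#' Render one synthetic frame with its ground truth
#'
#' Paints the channel band over the wall background, digitizes each
#' droplet as a filled disk (pixel-centre membership, no anti-aliasing),
#' adds speck debris, additive pixel noise and the global brightness
#' offset `brightness_drift_per_s * t`, clipping intensities to \[0, 1\].
#' Rendering is deterministic: the same `(spec, t)` always produces the
#' same raster, whatever the caller's RNG state.
#'
#' @param spec A `scene_spec`.
#' @param t Frame time in seconds (>= 0).
#' @param strict If `TRUE`, reject a render whose brightness drift pushes
#'   the (clipped) oil and droplet red-band values within 0.2 of each
#'   other, i.e. past threshold separability.
#' @return List with `frame` (a [new_frame()] object) and `truth` (data
#'   frame: `droplet_id`, `center_row`, `center_col`, `diameter_mm`,
#'   `diameter_px`; attribute `timestamp`). Every listed droplet lies
#'   fully inside the channel and the image.
#' @export
render_frame <- function(spec, t, strict = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (t < 0) stop("t must be >= 0")
  drift <- spec$brightness_drift_per_s * t
  if (strict) {
    oil_eff <- min(1, spec$oil_rgb[1] + drift)
    drop_eff <- min(1, spec$droplet_rgb[1] + drift)
    if (oil_eff - drop_eff < 0.2) {
      stop("brightness drift at t destroys oil/droplet separability")
    }
  }
  H <- spec$image_height
  W <- spec$image_width
  out <- with_seed(frame_seed(spec$seed, t), {
    truth <- draw_layout(spec, t)
    img <- array(rep(spec$wall_rgb, each = H * W), dim = c(H, W, 3))
    ch <- channel_rows(spec)
    for (k in 1:3) img[ch, , k] <- spec$oil_rgb[k]
    # droplets: filled disks by pixel-centre membership
    for (i in seq_len(nrow(truth))) {
      cr <- truth$center_row[i]
      cc <- truth$center_col[i]
      rad <- truth$diameter_px[i] / 2
      rr <- max(1, floor(cr - rad)):min(H, ceiling(cr + rad))
      cols <- max(1, floor(cc - rad)):min(W, ceiling(cc + rad))
      inside <- outer((rr - cr)^2, (cols - cc)^2, `+`) <= rad^2
      for (k in 1:3) {
        sub <- img[rr, cols, k]
        sub[inside] <- spec$droplet_rgb[k]
        img[rr, cols, k] <- sub
      }
    }
    # speck debris inside the channel, droplet-coloured, grown by a
    # random 4-neighbour walk from a seed pixel
    n_specks <- stats::rpois(1, spec$speck_density * H * W / 1000)
    for (s in seq_len(n_specks)) {
      area <- sample.int(spec$speck_max_area, 1)
      pr <- sample(ch, 1)
      pc <- sample.int(W, 1)
      pts <- matrix(c(pr, pc), 1, 2)
      while (nrow(pts) < area) {
        base <- pts[sample.int(nrow(pts), 1), ]
        stp <- neighbour_offsets(4L)[sample.int(4L, 1L), ]
        cand <- base + stp
        if (cand[1] >= 1 && cand[1] <= H && cand[2] >= 1 && cand[2] <= W) {
          pts <- unique(rbind(pts, cand))
        }
      }
      for (k in 1:3) img[cbind(pts, k)] <- spec$droplet_rgb[k]
    }
    if (spec$pixel_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$pixel_noise_sd)
    }
    list(img = img, truth = truth)
  })
  img <- pmin(pmax(out$img + drift, 0), 1)
  attr(out$truth, "timestamp") <- t
  list(
    frame = new_frame(img, timestamp = t,
                      frame_id = sprintf("frame_%06d", as.integer(round(t)))),
    truth = out$truth
  )
}

#' Render a timed series of synthetic frames
#'
#' Renders frames at `start, start + interval, ...` while `t <= duration`
#' (endpoint inclusive), delegating the schedule to
#' [sampling_schedule()]. With
#' `render = FALSE` only the ground truth is drawn (identical layout
#' draws, no rasters), which makes large Monte-Carlo series cheap.
#'
#' @param spec A `scene_spec`.
#' @param start,interval,duration Schedule in seconds (defaults 15, 15,
#'   225: 15 frames).
#' @param render If `FALSE`, each element carries `truth` only.
#' @return List of per-frame lists (`frame`, `truth`), empty when the
#'   schedule is empty.
#' @export
render_series <- function(spec, start = 15, interval = 15, duration = 225,
                          render = TRUE) {
  times <- sampling_schedule(sampling_plan(start, interval, duration))
  lapply(times, function(t) {
    if (render) {
      render_frame(spec, t)
    } else {
      truth <- with_seed(frame_seed(spec$seed, t), draw_layout(spec, t))
      attr(truth, "timestamp") <- t
      list(frame = NULL, truth = truth)
    }
  })
}

#' Ground-truth frame summaries of a synthetic series
#'
#' Convenience wrapper: draws the series layout (no rasters) and returns
#' the per-frame true droplet count and mean true diameter, the reference
#' against which the image pipeline is validated.
#'
#' @inheritParams render_series
#' @return Data frame: `t_s`, `droplet_count`, `mean_true_diameter_mm`.
#' @export
truth_series <- function(spec, start = 15, interval = 15, duration = 225) {
  series <- render_series(spec, start, interval, duration, render = FALSE)
  do.call(rbind, lapply(series, function(el) {
    data.frame(
      t_s = attr(el$truth, "timestamp"),
      droplet_count = nrow(el$truth),
      mean_true_diameter_mm =
        if (nrow(el$truth) > 0) mean(el$truth$diameter_mm) else NA_real_
    )
  }))
}

#' Write a rendered series to disk
#'
#' Writes `frame_{t:06d}.png` files plus a `ground_truth.csv` with one
#' row per droplet (`frame`, `t_s`, `droplet_id`, `center_row`,
#' `center_col`, `diameter_mm`, `diameter_px`).
#'
#' @param series Output of [render_series()] (with rasters).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the ground-truth data frame.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(series, function(el) {
    t <- el$frame$timestamp
    fname <- sprintf("frame_%06d.png", as.integer(round(t)))
    png::writePNG(el$frame$pixels, file.path(dir, fname))
    if (nrow(el$truth) == 0) return(NULL)
    cbind(frame = fname, t_s = t, el$truth)
  })
  gt <- do.call(rbind, rows)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(gt)
}
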