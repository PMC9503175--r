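test_that("scene specs are validated against their geometric invariants", {
  expect_s3_class(scene_spec(), "scene_spec")
  expect_error(scene_spec(channel_width_mm = 30), "fit")
  expect_error(scene_spec(droplet_rgb = c(0.8, 0.3, 0.6)), "0.2")
  expect_error(scene_spec(droplet_spacing_mm = 3), "spacing")
  expect_error(scene_spec(oil_rgb = c(1.2, 0.5, 0.3)), "\\[0, 1\\]")
})

test_that("ground-truth diameters convert exactly and sit inside the scene", {
  spec <- scene_spec(diameter_trend = c(3.5, 0, 0), diameter_jitter_sd = 0,
                     droplet_spacing_mm = 30, seed = 5)
  rf <- render_frame(spec, 0)
  expect_gte(nrow(rf$truth), 1)
  expect_equal(rf$truth$diameter_px, rep(3.5 * 17.128, nrow(rf$truth)))
  expect_equal(rf$truth$diameter_px[1], 59.948, tolerance = 1e-12)

  spec2 <- scene_spec(seed = 9)
  for (t in c(15, 120, 225)) {
    tr <- render_frame(spec2, t)$truth
    expect_equal(tr$diameter_px, tr$diameter_mm * spec2$px_per_mm)
    rad <- tr$diameter_px / 2
    expect_true(all(tr$center_col - rad >= 1 &
                    tr$center_col + rad <= spec2$image_width))
    half_ch <- spec2$channel_width_mm * spec2$px_per_mm / 2
    expect_true(all(rad < half_ch))
    expect_true(all(tr$diameter_mm < spec2$channel_width_mm))
  }
})

test_that("a noise-free render takes exactly three red-band values", {
  spec <- scene_spec(seed = 3)
  fr <- render_frame(spec, 30)$frame
  red <- sort(unique(as.numeric(extract_band(fr, "red"))))
  expect_equal(red, sort(c(spec$wall_rgb[1], spec$droplet_rgb[1],
                           spec$oil_rgb[1])))
})

test_that("rendering is deterministic and independent of the caller's RNG", {
  spec <- scene_spec(pixel_noise_sd = 0.03, speck_density = 0.02, seed = 11)
  set.seed(1)
  a <- render_frame(spec, 45)
  set.seed(99)
  b <- render_frame(spec, 45)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  # different seeds give different scenes
  c <- render_frame(scene_spec(pixel_noise_sd = 0.03, seed = 12), 45)
  expect_false(identical(a$frame$pixels, c$frame$pixels))
})

test_that("oil and droplet red values stay separable under mild pixel noise", {
  spec <- scene_spec(pixel_noise_sd = 0.03, seed = 21)
  rf <- render_frame(spec, 60)
  red <- extract_band(rf$frame, "red")
  droplet <- matrix(FALSE, spec$image_height, spec$image_width)
  for (i in seq_len(nrow(rf$truth))) {
    droplet <- droplet | digitized_disk(
      spec$image_height, spec$image_width,
      rf$truth$center_row[i], rf$truth$center_col[i],
      rf$truth$diameter_px[i] / 2)
  }
  roi <- channel_roi(spec)
  oil <- !droplet
  oil[-(roi[1]:roi[3]), ] <- FALSE
  expect_lt(max(red[droplet]), min(red[oil]))
})

test_that("droplet-coloured components in a clean render match the truth count", {
  spec <- scene_spec(seed = 31)
  for (t in c(15, 105, 225)) {
    rf <- render_frame(spec, t)
    red <- extract_band(rf$frame, "red")
    mask <- red == spec$droplet_rgb[1]
    expect_equal(max(label_components(mask)), nrow(rf$truth))
  }
})

test_that("series follow the sampling schedule and the quadratic trend", {
  spec <- scene_spec(diameter_jitter_sd = 0, seed = 41)
  series <- render_series(spec, 15, 15, 225, render = FALSE)
  expect_length(series, 15)
  expect_length(render_series(spec, 15, 15, 10), 0)

  ts <- truth_series(spec)
  expect_equal(ts$t_s, seq(15, 225, by = 15))
  # zero jitter: per-frame means lie exactly on the quadratic
  expect_equal(ts$mean_true_diameter_mm, trend_diameter(spec, ts$t_s),
               tolerance = 1e-12)
  # jitter displaces them
  tj <- truth_series(scene_spec(diameter_jitter_sd = 0.05, seed = 41))
  expect_false(isTRUE(all.equal(tj$mean_true_diameter_mm,
                                trend_diameter(spec, tj$t_s))))
})

test_that("brightness drift offsets the raster and strict mode rejects washout", {
  base <- scene_spec(seed = 51)
  drift <- scene_spec(brightness_drift_per_s = 0.001, seed = 51)
  f0 <- render_frame(base, 100)$frame$pixels
  f1 <- render_frame(drift, 100)$frame$pixels
  expect_equal(f1, pmin(f0 + 0.1, 1))
  # at t = 400 s the offset clips oil at 1 and closes the red gap
  washy <- scene_spec(brightness_drift_per_s = 0.002, seed = 51)
  expect_error(render_frame(washy, 400, strict = TRUE), "separability")
  expect_s3_class(render_frame(washy, 400)$frame, "drop_frame")
})

test_that("written series round-trip through PNG and ground_truth.csv", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(seed = 61)
  series <- render_series(spec, 15, 15, 45)
  gt <- write_series(series, dir)
  expect_setequal(list.files(dir, pattern = "png$"),
                  sprintf("frame_%06d.png", c(15, 30, 45)))
  back <- read_frame(file.path(dir, "frame_000030.png"))
  expect_equal(back$timestamp, 30)
  # 8-bit PNG quantization only
  expect_lt(max(abs(back$pixels - series[[2]]$frame$pixels)), 1 / 255)
  csv <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(csv), sum(vapply(series, function(s) nrow(s$truth), 1L)))
})
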