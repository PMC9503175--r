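test_that("noiseless quadratics are interpolated to coefficient precision", {
  t <- seq(15, 225, by = 15)
  truth <- c(4.04, -0.006, 9e-6)
  df <- data.frame(t_s = t, mean_diameter_mm = truth[1] + truth[2] * t +
                     truth[3] * t^2)
  fit <- fit_diameter_trend(df)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-7)
  expect_lt(fit$rmse, 1e-10)
  expect_equal(predict(fit, c(15, 225)),
               truth[1] + truth[2] * c(15, 225) + truth[3] * c(15, 225)^2,
               tolerance = 1e-9)

  const <- data.frame(t_s = t, mean_diameter_mm = rep(3.3, length(t)))
  fc <- fit_diameter_trend(const)
  expect_equal(unname(coef(fc)), c(3.3, 0, 0), tolerance = 1e-9)
  expect_error(fit_diameter_trend(df[1:2, ]), "at least 3")
})

test_that("the quadratic fit equals the closed-form normal-equation solution", {
  withr::local_seed(431)
  for (rep in 1:10) {
    t <- seq(15, 225, by = 15)
    y <- 4 - 0.005 * t + stats::rnorm(length(t), 0, 0.05)
    df <- data.frame(t_s = t, mean_diameter_mm = y)
    expect_equal(unname(coef(fit_diameter_trend(df))),
                 oracle_polyfit(t, y, 2), tolerance = 1e-8)
  }
})

test_that("trend fitting accepts frame summaries and NA means are dropped", {
  spec <- scene_spec(diameter_jitter_sd = 0, seed = 71)
  ts <- truth_series(spec)
  fit <- fit_diameter_trend(ts)
  expect_equal(unname(coef(fit)), spec$diameter_trend, tolerance = 1e-7)
  ts2 <- ts
  ts2$mean_diameter_mm <- ts2$mean_true_diameter_mm
  ts2$mean_diameter_mm[3] <- NA
  expect_equal(fit_diameter_trend(ts2)$n_points, 14)
})

test_that("fitted endpoint means track the truth over seeded jittered series", {
  err15 <- err225 <- a1 <- numeric(40)
  for (i in seq_len(40)) {
    spec <- scene_spec(diameter_jitter_sd = 0.05, seed = 1000 + i)
    fit <- fit_diameter_trend(truth_series(spec))
    pred <- predict(fit, c(15, 225))
    expected <- trend_diameter(spec, c(15, 225))
    err15[i] <- abs(pred[1] - expected[1])
    err225[i] <- abs(pred[2] - expected[2])
    a1[i] <- coef(fit)["a1"]
  }
  expect_lte(median(err15), 0.05)
  expect_lte(median(err225), 0.05)
  expect_true(all(a1 < 0))
})

test_that("the frequency proxy reports count trend signs", {
  df <- data.frame(t_s = c(15, 30, 45), n_droplets = c(5, 5, 5))
  expect_equal(frequency_proxy(df)$trend_sign, 0)
  df2 <- data.frame(t_s = c(15, 30, 45, 60), n_droplets = c(6, 5, 4, 3))
  fp <- frequency_proxy(df2)
  expect_equal(fp$trend_sign, -1)
  expect_lt(fp$slope, 0)
  expect_error(frequency_proxy(df[1, , drop = FALSE]), "at least 2")

  # a thinning droplet train in the generator drives the count down
  spec <- scene_spec(spacing_drift_mm_per_s = 0.05, seed = 81)
  expect_equal(frequency_proxy(truth_series(spec))$trend_sign, -1)
})

test_that("threshold sweeps find the stable count plateau between the bands", {
  spec <- scene_spec(diameter_jitter_sd = 0, seed = 91)
  rf <- render_frame(spec, 60)
  band <- crop_roi(extract_band(rf$frame, "red"), channel_roi(spec))
  n_true <- nrow(rf$truth)

  grid <- round(seq(0.05, 0.95, by = 0.025), 3)
  sw <- threshold_sweep(band, grid)
  inside <- grid > spec$droplet_rgb[1] & grid <= spec$oil_rgb[1]
  expect_true(all(sw$sweep$n_droplets[inside] == n_true))
  # below the droplet band nothing is foreground; above the oil band the
  # whole ROI floods into a single component
  expect_true(all(sw$sweep$n_droplets[grid <= spec$droplet_rgb[1]] == 0))
  expect_true(all(sw$sweep$n_droplets[grid > spec$oil_rgb[1]] == 1))
  expect_equal(sw$modal_count, n_true)
  # plateau midpoint of (0.45, 0.9]
  expect_equal(sw$recommended_thr, 0.675, tolerance = 0.026)

  nine <- threshold_sweep(band, round(seq(0.1, 0.9, by = 0.1), 3))
  expect_equal(nrow(nine$sweep), 9)

  blank <- threshold_sweep(matrix(0.9, 60, 60), round(seq(0.1, 0.9, by = 0.1), 3))
  expect_true(all(blank$sweep$n_droplets == 0))
  expect_null(blank$plateau)
  expect_true(is.na(blank$recommended_thr))
  expect_error(threshold_sweep(band, c(0.3, 0.2)), "increasing")
})

test_that("foreground area is monotone in the threshold on two-level images", {
  spec <- scene_spec(diameter_jitter_sd = 0, seed = 92)
  band <- crop_roi(extract_band(render_frame(spec, 120)$frame, "red"),
                   channel_roi(spec))
  grid <- seq(0.1, 0.9, by = 0.05)
  lt <- vapply(grid, function(th) sum(binarize(band, th, "foreground_lt")),
               numeric(1))
  ge <- vapply(grid, function(th) sum(binarize(band, th, "foreground_ge")),
               numeric(1))
  expect_true(all(diff(lt) >= 0))
  expect_true(all(diff(ge) <= 0))
})
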