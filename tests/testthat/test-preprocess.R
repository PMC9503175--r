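make_rgb <- function(r, g, b) {
  px <- array(0, dim = c(dim(r), 3))
  px[, , 1] <- r
  px[, , 2] <- g
  px[, , 3] <- b
  new_frame(px, timestamp = 0, frame_id = "t")
}

test_that("band extraction selects the requested colour plane unchanged", {
  r <- matrix(stats::runif(30), 5, 6)
  g <- matrix(0, 5, 6)
  b <- matrix(1, 5, 6)
  fr <- make_rgb(r, g, b)
  expect_equal(as.numeric(extract_band(fr, "red")), as.numeric(r))
  expect_equal(unique(as.numeric(extract_band(fr, "green"))), 0)
  expect_equal(unique(as.numeric(extract_band(fr, "blue"))), 1)
  expect_equal(dim(extract_band(fr, "red")), c(5, 6))
  expect_error(extract_band(fr, "alpha"))
  expect_error(new_frame(array(2, dim = c(2, 2, 3))), "\\[0, 1\\]")
})

test_that("band histogram counts are conserved", {
  const <- matrix(0.5, 10, 10)
  h <- band_histogram(const, bins = 16)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(sum(h$count), 100)

  two <- matrix(c(0.2, 0.8), 10, 10)
  h2 <- band_histogram(two, bins = 10)
  expect_equal(sum(h2$count > 0), 2)
  expect_equal(sum(h2$count), 100)
  expect_error(band_histogram(const, bins = 1), "bins")
})

test_that("binarization honours polarity and maps the threshold value to foreground", {
  v <- matrix(c(0.2, 0.7, 0.9, 0.69999), 2, 2)
  ge <- binarize(v, 0.7, "foreground_ge")
  expect_identical(as.vector(ge), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(binarize(matrix(0, 3, 3), 0.5, "foreground_ge")))
  # lt mask is the complement of ge except pixels exactly at thr
  lt <- binarize(v, 0.7, "foreground_lt")
  expect_identical(lt, !ge)
})

test_that("raising the threshold never adds foreground under foreground_ge", {
  withr::local_seed(411)
  v <- matrix(stats::runif(400), 20, 20)
  prev <- binarize(v, 0, "foreground_ge")
  for (thr in seq(0.1, 1, by = 0.1)) {
    cur <- binarize(v, thr, "foreground_ge")
    expect_true(all(!(cur & !prev)))
    prev <- cur
  }
})

test_that("ROI crop returns the sub-raster and a round-trippable offset", {
  v <- matrix(seq_len(640 * 480) / (640 * 480), 480, 640)
  expect_equal(dim(crop_roi(v, c(1, 1, 480, 640))), c(480, 640))
  sub <- crop_roi(v, c(101, 201, 110, 210))
  expect_equal(dim(sub), c(10, 10))
  off <- attr(sub, "roi_offset")
  for (p in list(c(1, 1), c(10, 10), c(3, 7))) {
    expect_equal(sub[p[1], p[2]], v[p[1] + off[1], p[2] + off[2]])
  }
  expect_error(crop_roi(v, c(0, 1, 10, 10)), "bounds")
  expect_error(crop_roi(v, c(1, 1, 481, 640)), "bounds")
})

test_that("small-object filtering clears only components below min_area", {
  a <- matrix(FALSE, 12, 12)
  a[2:3, 2] <- TRUE              # 2-pixel speck
  a[6:10, 6:10] <- TRUE          # 25-pixel square
  out <- remove_small_objects(a, min_area = 5)
  expect_equal(sum(out), 25)
  # a component of exactly min_area pixels is kept (strict < removal)
  expect_equal(sum(remove_small_objects(a, min_area = 25)), 25)
  expect_equal(sum(remove_small_objects(a, min_area = 26)), 0)
  expect_error(remove_small_objects(a, min_area = 0), "min_area")
})

test_that("component labelling matches the union-find oracle", {
  withr::local_seed(412)
  for (rep in 1:10) {
    a <- random_mask(24, 24, p = stats::runif(1, 0.3, 0.55), opened = FALSE)
    for (conn in c(8, 4)) {
      lab <- label_components(a, conn)
      ref <- oracle_label(a, conn)
      expect_equal(max(lab), max(ref))
      # identical partitions: same pixel set for every matched label
      expect_true(all(lab[ref == 0] == 0))
      for (k in seq_len(max(ref))) {
        expect_equal(length(unique(lab[ref == k])), 1)
      }
    }
  }
  # filtering keeps exactly the oracle's large components
  a <- random_mask(32, 32, p = 0.45, opened = FALSE)
  kept <- remove_small_objects(a, min_area = 8)
  ref <- oracle_label(a, 8)
  big <- which(tabulate(ref) >= 8)
  expect_identical(kept, matrix(ref %in% big, 32, 32))
})

test_that("thresholding a noise-free scene recovers the exact droplet pixel set", {
  spec <- scene_spec(diameter_jitter_sd = 0, seed = 42)
  rf <- render_frame(spec, 60)
  band <- crop_roi(extract_band(rf$frame, "red"), channel_roi(spec))
  off <- attr(band, "roi_offset")
  mask <- binarize(band, 0.7, "foreground_lt")
  truth_mask <- matrix(FALSE, nrow(band), ncol(band))
  for (i in seq_len(nrow(rf$truth))) {
    truth_mask <- truth_mask | digitized_disk(
      nrow(band), ncol(band),
      rf$truth$center_row[i] - off[1], rf$truth$center_col[i] - off[2],
      rf$truth$diameter_px[i] / 2)
  }
  expect_identical(unname(mask), unname(truth_mask))
  # the noise-removal stages barely perturb clean digitized disks
  cleaned <- remove_small_objects(opening(mask, struct_elem(3)), 25)
  expect_lt(sum(xor(cleaned, truth_mask)) / sum(truth_mask), 0.001)
})
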