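test_that("cube save/load round-trips bit-exactly in both dialects", {
  cube <- random_raw_cube(16, 16, 6, seed = 11)
  for (dialect in c("tiff", "json")) {
    path <- tempfile(fileext = if (dialect == "tiff") ".tif" else ".json")
    save_cube(cube, path, dialect)
    back <- load_cube(path, dialect)
    expect_identical(back$pixels, cube$pixels * 1.0)
    expect_equal(back$band_centers_nm, STANDARD_BANDS)
    expect_equal(back$bit_depth, 16L)
    expect_false(back$is_calibrated)
  }
})

test_that("calibrated cubes survive the json dialect exactly", {
  cube <- constant_cal_cube(c(0.1, 0.25, 0.3), h = 5, w = 7)
  cube$pixels[1, 1, 1] <- 1 / 3
  path <- tempfile(fileext = ".json")
  save_cube(cube, path, "json")
  expect_identical(load_cube(path, "json")$pixels, cube$pixels)
})

test_that("band-count mismatch and corrupt headers are descriptive errors", {
  cube <- random_raw_cube(8, 8, 6)
  path <- tempfile(fileext = ".tif")
  save_cube(cube, path, "tiff")
  # rewrite with 5 pages, keep the 6-band sidecar
  pages <- tiff::readTIFF(path, all = TRUE)
  tiff::writeTIFF(pages[1:5], path, bits.per.sample = 16L)
  expect_error(load_cube(path, "tiff"), "band-count mismatch")
  expect_error(load_cube(tempfile(), "tiff"), "not found")
  bad <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages[1:5], bad, bits.per.sample = 16L)
  jsonlite::write_json(list(oops = 1), paste0(bad, ".json"))
  expect_error(load_cube(bad, "tiff"), "corrupt sidecar")
})

test_that("cube constructor enforces its invariants", {
  px <- array(0, c(4, 4, 3))
  expect_error(msi_cube(px, c(500, 530)), "does not match")
  expect_error(msi_cube(px, c(530, 500, 570)), "strictly increasing")
  expect_error(msi_cube(array(-1, c(2, 2, 1)), 500), "raw cube")
  expect_error(msi_cube(array(1.5, c(2, 2, 1)), 500, is_calibrated = TRUE),
               "calibrated cube")
})

test_that("calibration follows the dark/reference ratio formula", {
  # I_raw = I_ref -> reflectance of the standard (0.20) everywhere
  frames <- calibration_frames(matrix(0, 4, 4), matrix(1000, 4, 4))
  raw <- msi_cube(array(1000, c(4, 4, 2)), c(500, 530))
  expect_equal(as.vector(calibrate(raw, frames)$pixels),
               rep(0.20, 32))
  # I_raw = I_dark -> 0
  frames2 <- calibration_frames(matrix(100, 4, 4), matrix(1100, 4, 4))
  raw2 <- msi_cube(array(100, c(4, 4, 2)), c(500, 530))
  expect_equal(as.vector(calibrate(raw2, frames2)$pixels), rep(0, 32))
  # (600 - 100) / (1100 - 100) * 0.2 = 0.10
  raw3 <- msi_cube(array(600, c(4, 4, 2)), c(500, 530))
  expect_equal(as.vector(calibrate(raw3, frames2)$pixels), rep(0.10, 32))
})

test_that("calibration is invariant to a global illumination gain", {
  withr::with_seed(5, {
    raw <- array(runif(64, 200, 4000), c(4, 4, 4))
    ref <- matrix(runif(16, 5000, 9000), 4, 4)
    dark <- matrix(runif(16, 50, 150), 4, 4)
  })
  g <- 3.7
  c1 <- calibrate(msi_cube(raw, STANDARD_BANDS[1:4]),
                  calibration_frames(dark, ref))
  c2 <- calibrate(msi_cube(g * raw, STANDARD_BANDS[1:4]),
                  calibration_frames(g * dark, g * ref))
  expect_equal(c1$pixels, c2$pixels, tolerance = 1e-12)
})

test_that("calibrating twice is an error; degenerate references handled", {
  raw <- random_raw_cube(4, 4, 2, bands = c(500, 530))
  frames <- calibration_frames(matrix(0, 4, 4), matrix(60000, 4, 4))
  cal <- calibrate(raw, frames)
  expect_error(calibrate(cal, frames), "already calibrated")
  # reference <= dark everywhere -> failure
  bad <- calibration_frames(matrix(100, 4, 4), matrix(100, 4, 4))
  expect_error(calibrate(raw, bad), "calibration failed")
  # a single bad pixel is zeroed and counted, not fatal
  ref <- matrix(60000, 4, 4); ref[2, 2] <- 0
  cal2 <- calibrate(raw, calibration_frames(matrix(100, 4, 4), ref))
  expect_equal(cal2$pixels[2, 2, 1], 0)
  expect_equal(attr(cal2, "n_invalid"), 2L)  # one pixel x two bands
  # shape mismatch
  expect_error(calibrate(raw, calibration_frames(matrix(0, 3, 3),
                                                 matrix(1, 3, 3))),
               "do not match")
})

test_that("per-band calibration frames are supported", {
  px <- array(0, c(2, 2, 2))
  px[, , 1] <- 600; px[, , 2] <- 350
  raw <- msi_cube(px, c(500, 530))
  dark <- array(100, c(2, 2, 2))
  ref <- array(0, c(2, 2, 2)); ref[, , 1] <- 1100; ref[, , 2] <- 600
  cal <- calibrate(raw, calibration_frames(dark, ref))
  expect_equal(as.vector(cal$pixels[, , 1]), rep(0.10, 4))
  expect_equal(as.vector(cal$pixels[, , 2]), rep(0.10, 4))
})

test_that("full-frame ROI is the identity mask", {
  cube <- constant_cal_cube(c(0.2, 0.3))
  roi <- segment_roi(cube, "full_frame")
  expect_true(all(roi$mask))
  expect_equal(dim(roi$mask), dim(cube$pixels)[1:2])
})

test_that("otsu ROI recovers a bright disc (Dice >= 0.95)", {
  cfg <- generator_config(image_size = c(64L, 64L), foreground = "disc",
                          noise_sd = 50, brightness_jitter_sd = 0,
                          band_jitter_sd = 0, contrast_jitter_sd = 0)
  s <- generate_sample(default_class_templates()$shank, cfg, seed = 9)
  cal <- calibrate(s$raw, s$frames)
  roi <- segment_roi(cal, "otsu_threshold")
  expect_gte(dice_coef(roi$mask, s$roi$mask), 0.95)
})

test_that("otsu on a constant band falls back to full frame with warning", {
  cube <- constant_cal_cube(rep(0.4, 6))
  expect_warning(roi <- segment_roi(cube, "otsu_threshold"), "constant")
  expect_true(all(roi$mask))
})
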