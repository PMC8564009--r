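worked_image <- matrix(c(0, 0, 1, 1,
                         0, 0, 1, 1,
                         0, 2, 2, 2,
                         2, 2, 3, 3), 4, 4, byrow = TRUE)

test_that("quantization bins [0,1] uniformly and respects the ROI", {
  m <- matrix(0.5, 3, 3)
  expect_true(all(quantize_band(m, n_levels = 4) == 2))
  m2 <- matrix(c(0, 0.999), 1, 2)
  expect_equal(as.vector(quantize_band(m2, n_levels = 2)), c(0L, 1L))
  # the boundary value 1 lands in the top bin, not one past it
  expect_equal(quantize_band(matrix(1, 1, 1), n_levels = 8)[1, 1], 7L)
  roi <- roi_mask(matrix(c(TRUE, FALSE), 2, 2))
  q <- quantize_band(matrix(0.1, 2, 2), roi, 4)
  expect_true(all(is.na(q[!roi$mask])) && all(!is.na(q[roi$mask])))
  expect_error(quantize_band(matrix(0.1, 2, 2),
                             roi_mask(matrix(FALSE, 2, 2))), "empty ROI")
})

test_that("horizontal pair counts match hand enumeration", {
  cfg <- glcm_config(n_levels = 2, distance = 1, angles_deg = 0,
                     symmetric = FALSE, average_over_angles = FALSE)
  g <- compute_glcm(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), cfg)
  expect_equal(g$g, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  cfg4 <- glcm_config(n_levels = 4, distance = 1, angles_deg = 0,
                      symmetric = FALSE, average_over_angles = FALSE)
  g4 <- compute_glcm(worked_image, cfg4)
  counts <- matrix(0, 4, 4)
  counts[1, 1] <- 2; counts[1, 2] <- 2; counts[2, 2] <- 2
  counts[1, 3] <- 1; counts[3, 3] <- 3; counts[3, 4] <- 1; counts[4, 4] <- 1
  expect_equal(g4$g, counts / 12)
})

test_that("worked 4x4 example yields the hand-derived statistics", {
  cfg <- glcm_config(n_levels = 4, distance = 1, angles_deg = 0,
                     symmetric = FALSE, average_over_angles = FALSE)
  s <- glcm_statistics(compute_glcm(worked_image, cfg))
  expect_equal(s[["contrast"]], 7 / 12, tolerance = 1e-12)
  expect_equal(s[["homogeneity"]], 9.7 / 12, tolerance = 1e-12)
  expect_equal(s[["energy"]], 1 / 6, tolerance = 1e-12)
})

test_that("symmetric GLCM equals (G + t(G)) / 2 of the asymmetric one", {
  lev <- withr::with_seed(3, matrix(sample(0:5, 100, TRUE), 10, 10))
  asym <- compute_glcm(lev, glcm_config(6, 1, 45, symmetric = FALSE))
  sym <- compute_glcm(lev, glcm_config(6, 1, 45, symmetric = TRUE))
  expect_equal(sym$g, (asym$g + t(asym$g)) / 2, tolerance = 1e-15)
  expect_equal(sym$g, t(sym$g))
})

test_that("GLCM entries are a probability distribution", {
  lev <- withr::with_seed(4, matrix(sample(0:7, 144, TRUE), 12, 12))
  g <- compute_glcm(lev, glcm_config(8, 2))
  expect_true(all(g$g >= 0))
  expect_equal(sum(g$g), 1, tolerance = 1e-12)
})

test_that("degenerate and extreme distributions hit the statistic bounds", {
  # constant image: point mass on the diagonal
  g <- compute_glcm(matrix(0L, 4, 4), glcm_config(n_levels = 2))
  s <- glcm_statistics(g)
  expect_equal(s[["homogeneity"]], 1)
  expect_equal(s[["contrast"]], 0)
  expect_equal(s[["energy"]], 1)
  expect_equal(s[["correlation"]], 0)   # zero variance -> defined as 0
  # checkerboard at distance 1, angle 0: perfect anticorrelation
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  s2 <- glcm_statistics(compute_glcm(cb, glcm_config(2, 1, 0)))
  expect_equal(s2[["correlation"]], -1, tolerance = 1e-12)
  expect_equal(s2[["correlation"]],
               brute_stats(brute_glcm(cb, 2, 1, 0, TRUE, TRUE))[["correlation"]])
})

test_that("unnormalized matrices are rejected", {
  fake <- structure(list(g = matrix(1, 2, 2), config = glcm_config(2)),
                    class = "glcm")
  expect_error(glcm_statistics(fake), "not normalized")
})

test_that("vectorized GLCM and statistics agree with brute force", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      h <- sample(5:32, 1); w <- sample(5:32, 1)
      n <- sample(2:8, 1); d <- sample(1:2, 1)
      sym <- sample(c(TRUE, FALSE), 1)
      lev <- matrix(sample(0:(n - 1), h * w, TRUE), h, w)
      if (rep %% 3 == 0) lev[sample(h * w, h)] <- NA  # ROI holes
      angles <- sample(c(0, 45, 90, 135), sample(1:4, 1))
      cfg <- glcm_config(n, d, angles, symmetric = sym,
                         average_over_angles = TRUE)
      got <- compute_glcm(lev, cfg)
      want <- brute_glcm(lev, n, d, angles, sym, TRUE)
      expect_equal(got$g, want, tolerance = 1e-12)
      expect_equal(glcm_statistics(got),
                   brute_stats(want), tolerance = 1e-12)
    }
  })
})

test_that("statistics are invariant to offsets that keep the bins", {
  bins <- withr::with_seed(6, matrix(sample(0:7, 64, TRUE), 8, 8))
  img <- (bins + 0.3) / 8            # pixels at 30% into their bin
  q1 <- quantize_band(img, n_levels = 8)
  q2 <- quantize_band(img + 0.05 / 8, n_levels = 8)  # sub-bin offset
  expect_identical(q1, q2)
  cfg <- glcm_config(8)
  expect_equal(glcm_statistics(compute_glcm(q1, cfg)),
               glcm_statistics(compute_glcm(q2, cfg)))
})

test_that("contrast is invariant under level reversal i -> N-1-i", {
  lev <- withr::with_seed(7, matrix(sample(0:5, 100, TRUE), 10, 10))
  cfg <- glcm_config(6)
  s1 <- glcm_statistics(compute_glcm(lev, cfg))
  s2 <- glcm_statistics(compute_glcm(5L - lev, cfg))
  expect_equal(s1[["contrast"]], s2[["contrast"]], tolerance = 1e-12)
  expect_equal(s1[["energy"]], s2[["energy"]], tolerance = 1e-12)
})

test_that("texture vector is 4 statistics per band, band-major", {
  cube6 <- cal_cube_from_bands(withr::with_seed(8, lapply(1:6, function(b)
    matrix(runif(256), 16, 16))))
  v <- extract_texture(cube6)
  expect_length(v, 24)
  expect_match(names(v)[1:4], "^tex500_")
  expect_equal(sub("^tex500_", "", names(v)[1:4]),
               c("homogeneity", "contrast", "energy", "correlation"))
  cube1 <- cal_cube_from_bands(list(matrix(runif(64), 8, 8)))
  expect_length(extract_texture(cube1), 4)
})

test_that("stripes raise contrast perpendicular to their orientation", {
  cfg <- small_gen_config(noise_sd = 0, brightness_jitter_sd = 0,
                          band_jitter_sd = 0, contrast_jitter_sd = 0)
  tpl <- default_class_templates()$shank   # vertical stripes (90 deg)
  s <- generate_sample(tpl, cfg, seed = 12)
  cal <- calibrate(s$raw, s$frames)
  lev <- quantize_band(cal$pixels[, , 1], n_levels = 64)
  c0 <- glcm_statistics(compute_glcm(lev, glcm_config(64, 1, 0)))[["contrast"]]
  c90 <- glcm_statistics(compute_glcm(lev, glcm_config(64, 1, 90)))[["contrast"]]
  expect_gt(c0, c90)
  noise <- cal_cube_from_bands(list(withr::with_seed(13,
    matrix(runif(1024), 32, 32))))
  s_noise <- extract_texture(noise, config = glcm_config(64, 1, 0, TRUE, TRUE))
  s_stripe <- glcm_statistics(compute_glcm(lev, glcm_config(64, 1, 90)))
  # i.i.d. noise has near-zero correlation; stripes are structured
  expect_lt(abs(s_noise[["tex500_correlation"]]), 0.2)
})
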