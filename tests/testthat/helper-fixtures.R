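STANDARD_BANDS <- c(500, 530, 570, 680, 760, 808)

# small random raw cube
random_raw_cube <- function(h = 16, w = 16, nb = 6, seed = 1,
                            bands = STANDARD_BANDS[seq_len(nb)]) {
  withr::with_seed(seed, {
    px <- array(sample(0:65535, h * w * nb, replace = TRUE), c(h, w, nb))
    msi_cube(px, bands)
  })
}

# small calibrated cube with given per-band constant values
constant_cal_cube <- function(values, h = 8, w = 8,
                              bands = STANDARD_BANDS[seq_along(values)]) {
  px <- array(rep(values, each = h * w), c(h, w, length(values)))
  msi_cube(px, bands, is_calibrated = TRUE)
}

# calibrated cube with arbitrary band matrices
cal_cube_from_bands <- function(band_list,
                                bands = STANDARD_BANDS[seq_along(band_list)]) {
  h <- nrow(band_list[[1]]); w <- ncol(band_list[[1]])
  px <- array(0, c(h, w, length(band_list)))
  for (b in seq_along(band_list)) px[, , b] <- band_list[[b]]
  msi_cube(px, bands, is_calibrated = TRUE)
}

# a fast, small generator configuration for tests
small_gen_config <- function(n_per_class = c(sirloin = 10L, flank = 8L,
                                             shank = 10L),
                             image_size = c(32L, 32L), seed = 1L, ...) {
  generator_config(image_size = image_size, n_per_class = n_per_class,
                   seed = seed, ...)
}

# two well-separated Gaussian blob classes as a feature_matrix
separable_blobs <- function(n_per_class = 20, p = 4, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
    colnames(x) <- paste0("f", seq_len(p))
    feature_matrix(x, rep("MS", p),
                   rep(c("a", "b"), each = n_per_class))
  })
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
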