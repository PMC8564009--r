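BAND_CENTERS_NM <- c(500, 530, 570, 680, 760, 808)

#' Class template for the synthetic generator
#'
#' Describes one tissue class by its mean reflectance at each band center
#' and by its spatial texture: `oriented_stripes` (white fascia bands with
#' a dominant fiber direction, shank-like), `marbling_blobs` (smoothed
#' random blob field, sirloin-like intramuscular fat) or `weak_noise`
#' (low-amplitude smooth random field, flank-like).
#'
#' @param name class name.
#' @param reflectance_profile mean reflectance per band, each in (0, 1).
#' @param texture_kind `"marbling_blobs"`, `"oriented_stripes"` or
#'   `"weak_noise"`.
#' @param texture_contrast texture amplitude relative to the mean, in
#'   `[0, 1)`.
#' @param stripe_angle_deg stripe orientation (degrees from horizontal;
#'   oriented_stripes only).
#' @param blob_density expected blobs per pixel (marbling only).
#' @return An object of class `class_template`.
#' @export
class_template <- function(name, reflectance_profile,
                           texture_kind = c("marbling_blobs",
                                            "oriented_stripes", "weak_noise"),
                           texture_contrast = 0.1,
                           stripe_angle_deg = 90, blob_density = 0.003) {
  texture_kind <- match.arg(texture_kind)
  stopifnot(all(reflectance_profile > 0), all(reflectance_profile < 1),
            texture_contrast >= 0, texture_contrast < 1)
  structure(list(name = name,
                 reflectance_profile = as.numeric(reflectance_profile),
                 texture_kind = texture_kind,
                 texture_contrast = texture_contrast,
                 stripe_angle_deg = stripe_angle_deg,
                 blob_density = blob_density),
            class = "class_template")
}

#' Default class templates
#'
#' Reflectance profiles at 500/530/570/680/760/808 nm chosen to reproduce
#' the qualitative ordering of the three cuts: all classes darkest at
#' 500 nm (strong myoglobin absorption), shank brightest overall (white
#' tendon and lipid), and sirloin with a pronounced relative dip at the
#' 760 nm band (water/deoxymyoglobin absorption). Textures: shank carries
#' oriented fascia stripes, sirloin blob marbling, flank only weak texture.
#'
#' @return Named list of three [class_template()] objects
#'   (sirloin, flank, shank).
#' @export
default_class_templates <- function() {
  list(
    sirloin = class_template("sirloin",
      reflectance_profile = c(0.12, 0.14, 0.15, 0.35, 0.26, 0.40),
      texture_kind = "marbling_blobs", texture_contrast = 0.25,
      blob_density = 0.003),
    flank = class_template("flank",
      reflectance_profile = c(0.14, 0.16, 0.18, 0.37, 0.38, 0.44),
      texture_kind = "weak_noise", texture_contrast = 0.08),
    shank = class_template("shank",
      reflectance_profile = c(0.18, 0.20, 0.22, 0.42, 0.48, 0.52),
      texture_kind = "oriented_stripes", texture_contrast = 0.30,
      stripe_angle_deg = 90))
}

#' Synthetic-dataset generator configuration
#'
#' Defaults emulate the study conditions: 6 bands at 500-808 nm, class
#' sizes (200 sirloin, 160 flank, 195 shank) totalling 555 samples, 16-bit
#' counts with additive Gaussian sensor noise (0.5% of full scale), a
#' smooth 2nd-order polynomial illumination field within +/-10%, dark level
#' at 5% of full scale, and a 20% diffuse reference standard. Frames
#' default to 128 x 128 pixels (the full 1290 x 960 sensor format is
#' supported but not the default). Per-sample jitter (common brightness sd
#' 8%, per-band sd 3%, texture-contrast sd 20%) provides within-class
#' variability.
#'
#' @param image_size `(height, width)` in pixels.
#' @param n_per_class named integer vector of samples per class.
#' @param noise_sd additive Gaussian noise sd in raw counts.
#' @param illumination_order polynomial order of the gain field (0 = flat).
#' @param illumination_amplitude approximate peak relative deviation of the
#'   gain field.
#' @param bit_depth sensor bit depth.
#' @param seed master seed.
#' @param class_templates named list of [class_template()]s.
#' @param separation_scale multiplier on between-class reflectance-profile
#'   differences (0 = classes spectrally identical).
#' @param band_amp_weights per-band multiplier on texture amplitude
#'   (texture is more visible in the short-wavelength bands).
#' @param brightness_jitter_sd,band_jitter_sd,contrast_jitter_sd per-sample
#'   multiplicative jitter standard deviations.
#' @param foreground `"full"` (tissue fills the frame) or `"disc"` (bright
#'   centered disc on a dark background, for ROI-segmentation tests).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(image_size = c(128L, 128L),
                             n_per_class = c(sirloin = 200L, flank = 160L,
                                             shank = 195L),
                             noise_sd = 0.005 * 65535,
                             illumination_order = 2L,
                             illumination_amplitude = 0.10,
                             bit_depth = 16L, seed = 1L,
                             class_templates = default_class_templates(),
                             separation_scale = 1,
                             band_amp_weights = c(1.2, 1.1, 1.0, 0.9,
                                                  0.85, 0.8),
                             brightness_jitter_sd = 0.08,
                             band_jitter_sd = 0.03,
                             contrast_jitter_sd = 0.2,
                             foreground = c("full", "disc")) {
  stopifnot(all(image_size >= 8), all(n_per_class >= 1),
            noise_sd >= 0, separation_scale >= 0,
            length(band_amp_weights) == length(BAND_CENTERS_NM),
            identical(sort(names(n_per_class)),
                      sort(names(class_templates))))
  structure(list(image_size = as.integer(image_size),
                 n_per_class = n_per_class,
                 noise_sd = noise_sd,
                 illumination_order = as.integer(illumination_order),
                 illumination_amplitude = illumination_amplitude,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 class_templates = class_templates,
                 separation_scale = separation_scale,
                 band_amp_weights = band_amp_weights,
                 brightness_jitter_sd = brightness_jitter_sd,
                 band_jitter_sd = band_jitter_sd,
                 contrast_jitter_sd = contrast_jitter_sd,
                 foreground = match.arg(foreground)),
            class = "generator_config")
}

#' Null-model generator configuration
#'
#' The default configuration with `separation_scale = 0` and every class
#' given the same weak-noise texture, so classes are statistically
#' indistinguishable and downstream classification accuracy should sit at
#' chance.
#'
#' @param ... overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
null_generator_config <- function(...) {
  cfg <- generator_config(...)
  cfg$separation_scale <- 0
  cfg$class_templates <- lapply(cfg$class_templates, function(tpl) {
    tpl$texture_kind <- "weak_noise"
    tpl$texture_contrast <- 0.08
    tpl$stripe_angle_deg <- 90
    tpl$blob_density <- 0.003
    tpl
  })
  cfg
}

# profile after scaling between-class differences about the across-class mean
scaled_profile <- function(template, config) {
  profs <- vapply(config$class_templates, `[[`, numeric(length(BAND_CENTERS_NM)),
                  "reflectance_profile")
  center <- rowMeans(profs)
  p <- center + config$separation_scale *
    (template$reflectance_profile - center)
  pmin(pmax(p, 0.01), 0.99)
}

# separable Gaussian smoothing with edge replication; kernel radius is
# truncated so arbitrarily small frames remain valid
gaussian_smooth <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  r <- max(1L, min(ceiling(3 * sigma), h - 1L, w - 1L))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  along <- function(m, n, idx_fun) {
    acc <- m * k[r + 1]
    for (o in seq_len(r)) {
      up <- pmin(pmax(seq_len(n) + o, 1L), n)
      dn <- pmin(pmax(seq_len(n) - o, 1L), n)
      acc <- acc + k[r + 1 + o] * idx_fun(m, up) +
        k[r + 1 - o] * idx_fun(m, dn)
    }
    acc
  }
  m <- along(m, h, function(m, i) m[i, , drop = FALSE])
  along(m, w, function(m, j) m[, j, drop = FALSE])
}

# standardized (mean 0, sd 1) smooth Gaussian random field
smooth_field <- function(h, w, sigma) {
  f <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w), sigma)
  (f - mean(f)) / stats::sd(f)
}

# standardized texture field for one sample; draws from the current RNG
texture_field <- function(template, h, w) {
  tf <- switch(template$texture_kind,
    oriented_stripes = {
      period <- stats::runif(1, 8, 16)
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- (template$stripe_angle_deg - 90) * pi / 180
      xc <- matrix(rep(seq_len(w), each = h), h, w)
      yc <- matrix(rep(seq_len(h), times = w), h, w)
      u <- xc * cos(ang) + yc * sin(ang)
      sign(sin(2 * pi * u / period + phase)) + 0.4 * smooth_field(h, w, 3)
    },
    marbling_blobs = {
      n_blobs <- stats::rpois(1, template$blob_density * h * w)
      img <- matrix(0, h, w)
      if (n_blobs > 0) {
        pos <- cbind(sample.int(h, n_blobs, replace = TRUE),
                     sample.int(w, n_blobs, replace = TRUE))
        img[pos] <- img[pos] + 1
      }
      gaussian_smooth(img, sigma = 4) + 0.15 * smooth_field(h, w, 3)
    },
    weak_noise = smooth_field(h, w, 3))
  s <- stats::sd(tf)
  if (s < .Machine$double.eps) tf * 0 else (tf - mean(tf)) / s
}

# smooth polynomial illumination gain field with mean 1; current RNG
gain_field <- function(h, w, order, amplitude) {
  if (order < 1 || amplitude <= 0) return(matrix(1, h, w))
  xc <- matrix(rep(seq_len(w), each = h), h, w) / w - 0.5
  yc <- matrix(rep(seq_len(h), times = w), h, w) / h - 0.5
  terms <- list(xc, yc)
  if (order >= 2) terms <- c(terms, list(xc^2, yc^2, xc * yc))
  coefs <- stats::runif(length(terms), -1, 1)
  g <- Reduce(`+`, Map(`*`, terms, coefs))
  rng <- max(abs(g))
  if (rng > 0) g <- g / rng * amplitude
  g <- 1 + g
  g / mean(g)
}

#' Generate one labeled synthetic sample
#'
#' Builds a per-band true reflectance field
#' `profile[b] * (1 + amplitude[b] * texture)` (texture shared across bands
#' with band-dependent amplitude), then images it through the measurement
#' model: raw counts = dark level + gain field x reflectance x photon
#' scale + Gaussian noise, quantized to the sensor bit depth. The matching
#' reference frame images the 20% diffuse standard through the same gain
#' field, and the dark frame the dark level alone, so [calibrate()]
#' recovers the reflectance field and cancels the illumination gradient.
#'
#' @param template a [class_template()].
#' @param config a [generator_config()].
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return List with `raw` (uncalibrated [msi_cube()]), `frames`
#'   ([calibration_frames()]), `roi` (ground-truth [roi_mask()]) and
#'   `truth` (jittered profile and texture parameters actually used).
#' @export
generate_sample <- function(template, config, seed = NULL) {
  run <- function() {
    h <- config$image_size[1]; w <- config$image_size[2]
    nb <- length(BAND_CENTERS_NM)
    full <- 2^config$bit_depth - 1
    dark_level <- 0.05 * full
    photon_scale <- 0.55 * full

    bright <- max(0.5, stats::rnorm(1, 1, config$brightness_jitter_sd))
    band_jit <- pmax(0.5, stats::rnorm(nb, 1, config$band_jitter_sd))
    contrast <- template$texture_contrast *
      max(0, stats::rnorm(1, 1, config$contrast_jitter_sd))
    profile <- pmin(pmax(scaled_profile(template, config) *
                           bright * band_jit, 0.01), 0.99)

    tex <- texture_field(template, h, w)
    mask <- if (config$foreground == "disc") {
      xc <- matrix(rep(seq_len(w), each = h), h, w) - (w + 1) / 2
      yc <- matrix(rep(seq_len(h), times = w), h, w) - (h + 1) / 2
      sqrt(xc^2 + yc^2) <= 0.42 * min(h, w)
    } else matrix(TRUE, h, w)

    gain <- gain_field(h, w, config$illumination_order,
                       config$illumination_amplitude)
    quantize_counts <- function(x) {
      if (config$noise_sd > 0) x <- x + stats::rnorm(length(x), 0,
                                                     config$noise_sd)
      round(pmin(pmax(x, 0), full))
    }
    px <- array(0, c(h, w, nb))
    for (b in seq_len(nb)) {
      amp <- contrast * config$band_amp_weights[b]
      refl <- pmin(pmax(profile[b] * (1 + amp * tex), 0.001), 0.999)
      refl[!mask] <- 0.02
      px[, , b] <- quantize_counts(dark_level + gain * refl * photon_scale)
    }
    dark <- matrix(quantize_counts(rep(dark_level, h * w)), h, w)
    reference <- matrix(quantize_counts(dark_level +
                                          gain * 0.20 * photon_scale), h, w)
    list(raw = msi_cube(px, BAND_CENTERS_NM, config$bit_depth),
         frames = calibration_frames(dark, reference,
                                     reference_reflectance = 0.20),
         roi = roi_mask(mask),
         truth = list(class = template$name, profile = profile,
                      texture_kind = template$texture_kind,
                      texture_contrast = contrast,
                      stripe_angle_deg = template$stripe_angle_deg,
                      brightness_jitter = bright, gain = gain))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a labeled dataset of synthetic cubes
#'
#' Draws `n_per_class` samples per class with seeded per-sample jitter and
#' returns calibrated (or raw) cubes together with a manifest recording
#' every sample's ground-truth parameters.
#'
#' @param config a [generator_config()].
#' @param calibrated return calibrated cubes (default); if `FALSE`, raw
#'   cubes with their calibration frames.
#' @return List with `samples` (list of cubes, or of `(raw, frames, roi)`
#'   lists when `calibrated = FALSE`), `labels` (factor, levels sirloin /
#'   flank / shank), `rois`, and `manifest` (data frame: id, class, seed,
#'   jittered profile, texture parameters).
#' @export
generate_dataset <- function(config = generator_config(),
                             calibrated = TRUE) {
  classes <- names(config$n_per_class)
  labels <- factor(rep(classes, config$n_per_class), levels = classes)
  n <- length(labels)
  seeds <- withr::with_seed(config$seed, sample.int(2147483646L, n))
  samples <- vector("list", n)
  rois <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- config$class_templates[[as.character(labels[i])]]
    s <- generate_sample(tpl, config, seed = seeds[i])
    rois[[i]] <- s$roi
    samples[[i]] <- if (calibrated) calibrate(s$raw, s$frames)
                    else s[c("raw", "frames", "roi")]
    rows[[i]] <- data.frame(id = i, class = s$truth$class,
                            seed = seeds[i],
                            texture_kind = s$truth$texture_kind,
                            texture_contrast = s$truth$texture_contrast,
                            stripe_angle_deg = s$truth$stripe_angle_deg,
                            brightness_jitter = s$truth$brightness_jitter,
                            t(stats::setNames(s$truth$profile,
                                              sprintf("profile_%gnm",
                                                      BAND_CENTERS_NM))))
  }
  list(samples = samples, labels = labels, rois = rois,
       manifest = do.call(rbind, rows))
}
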