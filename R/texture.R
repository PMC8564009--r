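#' GLCM configuration
#'
#' Settings for gray-level co-occurrence matrix construction: the number of
#' quantization levels, the pixel offset distance, the set of canonical
#' directions, whether the matrix is symmetrized (pairs counted in both
#' orders), and whether the per-direction matrices are averaged into one.
#' The defaults (64 levels, distance 1, all four directions averaged,
#' symmetric) give a single rotation-robust value per statistic per band.
#'
#' @param n_levels number of gray levels `N` (>= 2).
#' @param distance pixel offset distance (>= 1).
#' @param angles_deg non-empty subset of `c(0, 45, 90, 135)`.
#' @param symmetric count each pair in both orders.
#' @param average_over_angles average the normalized per-angle matrices.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 64L, distance = 1L,
                        angles_deg = c(0, 45, 90, 135),
                        symmetric = TRUE, average_over_angles = TRUE) {
  stopifnot(n_levels >= 2, distance >= 1, length(angles_deg) >= 1,
            all(angles_deg %in% c(0, 45, 90, 135)),
            !anyDuplicated(angles_deg))
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 angles_deg = as.numeric(angles_deg),
                 symmetric = isTRUE(symmetric),
                 average_over_angles = isTRUE(average_over_angles)),
            class = "glcm_config")
}

#' Uniform gray-level quantization of a reflectance band
#'
#' Maps reflectance in `[0, 1]` to integer levels `0 .. n_levels - 1` by
#' uniform binning: `level = floor(clip(x, 0, 1 - eps) * n_levels)`, so the
#' boundary value 1 falls in the top bin. Pixels outside the ROI are set to
#' `NA` and ignored by [compute_glcm()].
#'
#' @param band_image numeric matrix of reflectance in `[0, 1]`.
#' @param roi an [roi_mask()] or `NULL` for the full frame.
#' @param n_levels number of levels.
#' @return Integer matrix of levels with `NA` outside the ROI.
#' @export
quantize_band <- function(band_image, roi = NULL, n_levels = 64L) {
  stopifnot(is.matrix(band_image), n_levels >= 2)
  mask <- if (is.null(roi)) matrix(TRUE, nrow(band_image), ncol(band_image))
          else roi$mask
  stopifnot(identical(dim(mask), dim(band_image)))
  if (!any(mask)) stop("empty ROI: no pixels to quantize")
  lev <- floor(pmin(pmax(band_image, 0), 1 - 1e-9) * n_levels)
  lev[!mask] <- NA
  storage.mode(lev) <- "integer"
  lev
}

# (row, col) offset for a canonical GLCM direction at the given distance;
# rows increase downward, origin top-left
angle_offset <- function(angle_deg, distance) {
  switch(as.character(angle_deg),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("unsupported angle: ", angle_deg))
}

glcm_one_angle <- function(levels, n_levels, dr, dc) {
  h <- nrow(levels); w <- ncol(levels)
  ri <- seq_len(h); ci <- seq_len(w)
  ri <- ri[ri + dr >= 1 & ri + dr <= h]
  ci <- ci[ci + dc >= 1 & ci + dc <= w]
  if (length(ri) == 0 || length(ci) == 0) {
    stop(sprintf("no valid pixel pairs for offset (%d, %d)", dr, dc))
  }
  a <- levels[ri, ci, drop = FALSE]
  b <- levels[ri + dr, ci + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) {
    stop(sprintf("no valid pixel pairs for offset (%d, %d)", dr, dc))
  }
  counts <- tabulate(a[keep] * n_levels + b[keep] + 1L,
                     nbins = n_levels * n_levels)
  matrix(counts, nrow = n_levels, byrow = TRUE)
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts how often a pixel of level `i` co-occurs with a pixel of level `j`
#' at the configured offset(s), skipping `NA` (background) pixels, then
#' normalizes to a probability matrix `g(i, j)` summing to 1. With
#' `symmetric = TRUE` each pair is counted in both orders; with
#' `average_over_angles = TRUE` the normalized matrices of the configured
#' directions are averaged.
#'
#' @param levels integer level matrix from [quantize_band()].
#' @param config a [glcm_config()].
#' @return An object of class `glcm`: list with the probability matrix `g`
#'   and the `config`. When `average_over_angles = FALSE` and several angles
#'   are configured, a list of `glcm` objects (one per angle).
#' @export
compute_glcm <- function(levels, config = glcm_config()) {
  stopifnot(is.matrix(levels), inherits(config, "glcm_config"))
  n <- config$n_levels
  if (any(levels < 0 | levels >= n, na.rm = TRUE)) {
    stop("levels must lie in 0 .. n_levels - 1")
  }
  per_angle <- lapply(config$angles_deg, function(ang) {
    off <- angle_offset(ang, config$distance)
    cmat <- glcm_one_angle(levels, n, off[1], off[2])
    if (config$symmetric) cmat <- cmat + t(cmat)
    cmat / sum(cmat)
  })
  as_glcm <- function(g) structure(list(g = g, config = config),
                                   class = "glcm")
  if (config$average_over_angles || length(per_angle) == 1L) {
    as_glcm(Reduce(`+`, per_angle) / length(per_angle))
  } else {
    lapply(per_angle, as_glcm)
  }
}

#' Haralick statistics of a GLCM
#'
#' The four texture statistics used per spectral band, for a normalized
#' co-occurrence matrix `g(i, j)` with levels `i, j = 0 .. N-1`:
#' \describe{
#'   \item{homogeneity}{`sum g(i,j) / (1 + (i - j)^2)` — concentration of
#'     mass near the diagonal (1 iff all mass is on the diagonal).}
#'   \item{contrast}{`sum (i - j)^2 g(i,j)` — local gray-level variation.}
#'   \item{energy}{`sum g(i,j)^2` (angular second moment) — uniformity of
#'     the pair distribution (1 iff a point mass).}
#'   \item{correlation}{`(sum i j g(i,j) - mu_x mu_y) / (sigma_x sigma_y)`
#'     — gray-tone linear dependence in `[-1, 1]`, defined as 0 when either
#'     marginal variance vanishes.}
#' }
#'
#' @param glcm a `glcm` object from [compute_glcm()].
#' @return Named numeric vector
#'   `(homogeneity, contrast, energy, correlation)`.
#' @export
glcm_statistics <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  g <- glcm$g
  if (abs(sum(g) - 1) > 1e-8) stop("GLCM is not normalized (sum != 1)")
  n <- nrow(g)
  i <- matrix(0:(n - 1), n, n)          # row index
  j <- t(i)                             # col index
  d2 <- (i - j)^2
  homog <- sum(g / (1 + d2))
  contrast <- sum(d2 * g)
  energy <- sum(g^2)
  mu_x <- sum(i * g); mu_y <- sum(j * g)
  var_x <- sum((i - mu_x)^2 * g); var_y <- sum((j - mu_y)^2 * g)
  corr <- if (var_x <= .Machine$double.eps || var_y <= .Machine$double.eps) 0
          else (sum(i * j * g) - mu_x * mu_y) / sqrt(var_x * var_y)
  c(homogeneity = homog, contrast = contrast, energy = energy,
    correlation = corr)
}

#' Per-band texture feature vector of a cube
#'
#' Quantizes each band, builds its GLCM and evaluates the four Haralick
#' statistics, yielding `4 * n_bands` texture features (24 for a six-band
#' cube). Features are ordered band-major, then
#' (homogeneity, contrast, energy, correlation), and named
#' `tex<band nm>_<statistic>`.
#'
#' @param cube a calibrated [msi_cube()].
#' @param roi an [roi_mask()] or `NULL` for full frame.
#' @param config a [glcm_config()]; must average over angles (or use a
#'   single angle) so that each band yields exactly four values.
#' @return Named numeric vector of length `4 * n_bands`.
#' @export
extract_texture <- function(cube, roi = NULL, config = glcm_config()) {
  stopifnot(inherits(cube, "msi_cube"))
  if (!cube$is_calibrated) stop("texture extraction requires a calibrated cube")
  if (!config$average_over_angles && length(config$angles_deg) > 1L) {
    stop("extract_texture needs average_over_angles = TRUE or a single angle")
  }
  stats <- c("homogeneity", "contrast", "energy", "correlation")
  out <- lapply(seq_len(n_bands(cube)), function(b) {
    lev <- quantize_band(cube$pixels[, , b], roi, config$n_levels)
    glcm_statistics(compute_glcm(lev, config))
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- as.vector(outer(stats, cube$band_centers_nm,
                              function(s, w) sprintf("tex%g_%s", w, s)))
  v
}
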