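#' Construct a multispectral image cube
#'
#' A cube is the raw measurement unit of snapshot multispectral imaging: a
#' stack of co-registered single-band images, here stored as an
#' `height x width x n_bands` array together with the band-center
#' wavelengths. Raw cubes hold integer sensor counts in
#' `[0, 2^bit_depth - 1]`; calibrated cubes hold relative reflectance in
#' `[0, 1]` (see [calibrate()]).
#'
#' @param pixels numeric array `height x width x n_bands` (a matrix is
#'   accepted for a single-band cube).
#' @param band_centers_nm strictly increasing vector of band-center
#'   wavelengths in nanometres, one per band.
#' @param bit_depth sensor bit depth of raw counts (default 16).
#' @param is_calibrated `TRUE` if `pixels` are reflectances in `[0, 1]`.
#' @return An object of class `msi_cube`.
#' @seealso [calibrate()], [save_cube()], [load_cube()]
#' @export
msi_cube <- function(pixels, band_centers_nm, bit_depth = 16L,
                     is_calibrated = FALSE) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  band_centers_nm <- as.numeric(band_centers_nm)
  if (dim(pixels)[3] != length(band_centers_nm)) {
    stop("number of bands (", dim(pixels)[3], ") does not match ",
         "band_centers_nm (", length(band_centers_nm), ")")
  }
  if (length(band_centers_nm) > 1 && any(diff(band_centers_nm) <= 0)) {
    stop("band_centers_nm must be strictly increasing")
  }
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (is_calibrated) {
    if (min(pixels) < 0 || max(pixels) > 1) {
      stop("calibrated cube must have pixels in [0, 1]")
    }
  } else {
    if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
      stop("raw cube must have pixels in [0, 2^bit_depth - 1]")
    }
  }
  structure(list(pixels = pixels,
                 band_centers_nm = band_centers_nm,
                 bit_depth = as.integer(bit_depth),
                 is_calibrated = isTRUE(is_calibrated)),
            class = "msi_cube")
}

#' @export
print.msi_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<msi_cube> %d x %d pixels, %d band(s) [%s nm], %s\n",
              d[1], d[2], d[3], paste(x$band_centers_nm, collapse = "/"),
              if (x$is_calibrated) "calibrated reflectance"
              else sprintf("raw %d-bit counts", x$bit_depth)))
  invisible(x)
}

n_bands <- function(cube) dim(cube$pixels)[3]

#' Dark and diffuse-reference calibration frames
#'
#' Holds the dark-response frame (sensor counts with the light path blocked)
#' and the frame of a diffuse reflectance standard, plus that standard's
#' nominal reflectance (20% for the usual gray standard). Frames may be a
#' single `height x width` matrix shared by all bands, or a
#' `height x width x n_bands` array with per-band frames.
#'
#' @param dark,reference numeric matrix or 3-d array of sensor counts.
#' @param reference_reflectance nominal reflectance of the standard,
#'   in `(0, 1]` (default 0.20).
#' @return An object of class `calibration_frames`.
#' @export
calibration_frames <- function(dark, reference, reference_reflectance = 0.20) {
  stopifnot(is.numeric(dark), is.numeric(reference),
            length(reference_reflectance) == 1,
            reference_reflectance > 0, reference_reflectance <= 1)
  if (!identical(dim(dark), dim(reference))) {
    stop("dark and reference frames must have identical dimensions")
  }
  structure(list(dark = dark, reference = reference,
                 reference_reflectance = reference_reflectance),
            class = "calibration_frames")
}

frame_band <- function(frame, b) {
  if (length(dim(frame)) == 3L) frame[, , b] else frame
}

#' Reflectance calibration of a raw cube
#'
#' Converts raw counts to relative reflectance band by band as the pointwise
#' ratio of dark-corrected intensities,
#' `R = (I_raw - I_dark) / (I_ref - I_dark) * reference_reflectance`,
#' which also cancels smooth illumination inhomogeneity because sample and
#' reference see the same gain field. The result is clipped to `[0, 1]`.
#' Pixels where the reference does not exceed the dark response carry no
#' usable signal; they are set to 0 and counted in the `n_invalid` attribute.
#'
#' @param raw an uncalibrated [msi_cube()].
#' @param frames a [calibration_frames()] object with matching spatial
#'   (and, if per-band, spectral) dimensions.
#' @return A calibrated `msi_cube` with reflectance in `[0, 1]` and an
#'   `n_invalid` attribute giving the number of flagged pixels.
#' @export
calibrate <- function(raw, frames) {
  stopifnot(inherits(raw, "msi_cube"), inherits(frames, "calibration_frames"))
  if (raw$is_calibrated) stop("cube is already calibrated")
  d <- dim(raw$pixels)
  fd <- dim(frames$dark)
  if (!identical(fd[1:2], d[1:2]) ||
      (length(fd) == 3L && fd[3] != d[3])) {
    stop("calibration frame dimensions do not match the cube")
  }
  out <- array(0, d)
  n_invalid <- 0L
  for (b in seq_len(d[3])) {
    dk <- frame_band(frames$dark, b)
    rf <- frame_band(frames$reference, b)
    denom <- rf - dk
    bad <- denom <= 0
    denom[bad] <- 1          # value irrelevant, overwritten below
    r <- (raw$pixels[, , b] - dk) / denom * frames$reference_reflectance
    r[bad] <- 0
    n_invalid <- n_invalid + sum(bad)
    out[, , b] <- pmin(pmax(r, 0), 1)
  }
  if (n_invalid >= prod(d[1:2]) * d[3]) {
    stop("calibration failed: reference does not exceed dark anywhere")
  }
  cal <- msi_cube(out, raw$band_centers_nm, raw$bit_depth,
                  is_calibrated = TRUE)
  attr(cal, "n_invalid") <- n_invalid
  cal
}

#' Region-of-interest mask
#'
#' @param mask logical matrix, `TRUE` for foreground pixels.
#' @param min_fraction minimum fraction of pixels that must be foreground.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, min_fraction = 0) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (mean(mask) < min_fraction) {
    stop(sprintf("ROI covers %.1f%% of pixels, below min_fraction %.1f%%",
                 100 * mean(mask), 100 * min_fraction))
  }
  structure(list(mask = mask, min_fraction = min_fraction),
            class = "roi_mask")
}

#' Select the foreground region of a calibrated cube
#'
#' `full_frame` uses every pixel. `otsu_threshold` applies Otsu's threshold
#' to one band (by default the 680 nm band, where tissue/background contrast
#' is strongest) and keeps the largest connected bright component. A
#' degenerate (constant) band cannot be thresholded; it falls back to the
#' full frame with a warning.
#'
#' @param cube a calibrated [msi_cube()].
#' @param method `"full_frame"` or `"otsu_threshold"`.
#' @param band_index band used for thresholding; default is the band whose
#'   center is closest to 680 nm.
#' @param min_fraction passed to [roi_mask()].
#' @return An [roi_mask()].
#' @export
segment_roi <- function(cube, method = c("full_frame", "otsu_threshold"),
                        band_index = NULL, min_fraction = 0) {
  stopifnot(inherits(cube, "msi_cube"))
  method <- match.arg(method)
  d <- dim(cube$pixels)
  if (method == "full_frame") {
    return(roi_mask(matrix(TRUE, d[1], d[2]), min_fraction))
  }
  if (!cube$is_calibrated) stop("otsu_threshold requires a calibrated cube")
  if (is.null(band_index)) {
    band_index <- which.min(abs(cube$band_centers_nm - 680))
  }
  band <- cube$pixels[, , band_index]
  if (max(band) - min(band) < .Machine$double.eps) {
    warning("band ", band_index, " is constant; falling back to full_frame")
    return(roi_mask(matrix(TRUE, d[1], d[2]), min_fraction))
  }
  thr <- EBImage::otsu(EBImage::Image(band), range = c(0, 1), levels = 256L)
  fg <- band > thr
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- EBImage::imageData(lab)
  if (max(lab) >= 1) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    fg <- lab == which.max(areas)
  }
  roi_mask(matrix(as.logical(fg), d[1], d[2]), min_fraction)
}

#' Write a multispectral cube to disk
#'
#' Two dialects are supported. `"tiff"` writes a multi-page TIFF (one
#' 16-bit grayscale page per band for raw cubes, 32-bit float pages for
#' calibrated cubes) plus a JSON sidecar `<path>.json` holding
#' `band_centers_nm`, `bit_depth` and `is_calibrated`. `"json"` writes a
#' single self-describing JSON archive with the same keys plus the pixel
#' array. Integer rasters round-trip bit-exactly in both dialects.
#'
#' @param cube an [msi_cube()].
#' @param path output file path.
#' @param dialect `"tiff"` or `"json"`.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path, dialect = c("tiff", "json")) {
  stopifnot(inherits(cube, "msi_cube"))
  dialect <- match.arg(dialect)
  header <- list(band_centers_nm = cube$band_centers_nm,
                 bit_depth = cube$bit_depth,
                 is_calibrated = cube$is_calibrated)
  if (dialect == "tiff") {
    pages <- lapply(seq_len(n_bands(cube)), function(b) cube$pixels[, , b])
    if (cube$is_calibrated) {
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    } else {
      # tiff stores [0,1]; scale counts by the 16-bit full scale so that
      # integer counts survive the round trip exactly
      tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                      bits.per.sample = 16L)
    }
    jsonlite::write_json(header, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    header$dim <- dim(cube$pixels)
    header$pixels <- as.vector(cube$pixels)
    # 17 significant digits: doubles round-trip exactly through the text
    jsonlite::write_json(header, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Read a multispectral cube written by [save_cube()]
#'
#' @param path file path.
#' @param dialect `"tiff"` or `"json"`.
#' @return An [msi_cube()].
#' @export
load_cube <- function(path, dialect = c("tiff", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cube file not found: ", path)
  if (dialect == "tiff") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("missing sidecar header: ", sidecar)
    header <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    req <- c("band_centers_nm", "bit_depth", "is_calibrated")
    if (!all(req %in% names(header))) {
      stop("corrupt sidecar header (need ",
           paste(req, collapse = ", "), "): ", sidecar)
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(header$band_centers_nm)) {
      stop("band-count mismatch: file has ", length(pages),
           " page(s) but header declares ",
           length(header$band_centers_nm), " band(s)")
    }
    px <- array(0, c(dim(pages[[1]]), length(pages)))
    for (b in seq_along(pages)) {
      p <- pages[[b]]
      if (!isTRUE(header$is_calibrated)) p <- round(p * 65535)
      px[, , b] <- p
    }
  } else {
    header <- jsonlite::read_json(path, simplifyVector = TRUE)
    req <- c("band_centers_nm", "bit_depth", "is_calibrated", "dim", "pixels")
    if (!all(req %in% names(header))) {
      stop("corrupt cube archive (need ",
           paste(req, collapse = ", "), "): ", path)
    }
    if (length(header$pixels) != prod(header$dim)) {
      stop("band-count mismatch: archive has ", length(header$pixels),
           " values but dim declares ", prod(header$dim))
    }
    px <- array(as.numeric(header$pixels), header$dim)
  }
  msi_cube(px, header$band_centers_nm, header$bit_depth,
           isTRUE(header$is_calibrated))
}
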