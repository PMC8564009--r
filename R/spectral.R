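# Linear RGB -> CIEXYZ transfer matrix (D65-referenced primaries)
XYZ_MATRIX <- matrix(c(0.412453, 0.357580, 0.180423,
                       0.212671, 0.715160, 0.072169,
                       0.019334, 0.119193, 0.950227),
                     nrow = 3, byrow = TRUE)

#' Default white point: the XYZ of the unit (1, 1, 1) RGB stimulus,
#' i.e. the row sums of the RGB->XYZ matrix (a D65-like point).
#' @export
default_white_point <- function() as.vector(XYZ_MATRIX %*% c(1, 1, 1))

#' Band-to-channel mapping for CIELAB conversion
#'
#' Selects which cube bands feed the R, G and B channels of the RGB->XYZ
#' conversion. The default picks the band centers closest to the red, green
#' and blue primaries among the six standard bands: R <- 680 nm,
#' G <- 570 nm, B <- 500 nm.
#'
#' @param r_band_nm,g_band_nm,b_band_nm three distinct wavelengths, each of
#'   which must match a cube band center.
#' @return An object of class `rgb_mapping`.
#' @export
rgb_mapping <- function(r_band_nm = 680, g_band_nm = 570, b_band_nm = 500) {
  w <- c(r_band_nm, g_band_nm, b_band_nm)
  stopifnot(length(w) == 3, !anyDuplicated(w))
  structure(list(r_band_nm = r_band_nm, g_band_nm = g_band_nm,
                 b_band_nm = b_band_nm), class = "rgb_mapping")
}

#' Mean ROI reflectance per band (the "MS" spectral feature set)
#'
#' @param cube a calibrated [msi_cube()].
#' @param roi an [roi_mask()] or `NULL` for the full frame.
#' @return Named numeric vector of length `n_bands`
#'   (`ms<band nm>` per band, cube band order).
#' @export
ms_features <- function(cube, roi = NULL) {
  stopifnot(inherits(cube, "msi_cube"))
  if (!cube$is_calibrated) stop("ms_features requires a calibrated cube")
  d <- dim(cube$pixels)
  mask <- if (is.null(roi)) matrix(TRUE, d[1], d[2]) else roi$mask
  if (!any(mask)) stop("empty ROI")
  v <- vapply(seq_len(d[3]),
              function(b) mean(cube$pixels[, , b][mask]), numeric(1))
  names(v) <- sprintf("ms%g", cube$band_centers_nm)
  v
}

#' Linear RGB to CIEXYZ tristimulus values
#'
#' Multiplies the (linear, un-gamma'd) RGB triple by the fixed 3x3 transfer
#' matrix. Reflectance inputs are physical, so no display companding is
#' applied.
#'
#' @param rgb numeric triple with components in `[0, 1]`.
#' @return Numeric triple `(X, Y, Z)`.
#' @export
rgb_to_xyz <- function(rgb) {
  stopifnot(length(rgb) == 3, all(is.finite(rgb)))
  if (any(rgb < 0 | rgb > 1)) stop("RGB components must lie in [0, 1]")
  xyz <- as.vector(XYZ_MATRIX %*% rgb)
  names(xyz) <- c("X", "Y", "Z")
  xyz
}

# CIE compression function: cube root above the knee, linear below
lab_f <- function(x) {
  knee <- (24 / 116)^3
  ifelse(x > knee, x^(1 / 3), (841 / 108) * x + 16 / 116)
}

#' CIEXYZ to CIELAB
#'
#' `L* = 116 f(Y/Yn) - 16`, `a* = 500 [f(X/Xn) - f(Y/Yn)]`,
#' `b* = 200 [f(Y/Yn) - f(Z/Zn)]`, where `f` is the cube root above the
#' knee `(24/116)^3` and the linear segment `841/108 x + 16/116` below it
#' (the two branches agree at the knee).
#'
#' @param xyz numeric triple `(X, Y, Z)`.
#' @param white_point reference white `(Xn, Yn, Zn)`, componentwise
#'   positive; defaults to [default_white_point()].
#' @return Named numeric triple `(L_star, a_star, b_star)`.
#' @export
xyz_to_lab <- function(xyz, white_point = default_white_point()) {
  stopifnot(length(xyz) == 3, length(white_point) == 3)
  if (any(white_point <= 0)) stop("white point must be componentwise positive")
  f <- unname(lab_f(xyz / white_point))
  c(L_star = 116 * f[2] - 16,
    a_star = 500 * (f[1] - f[2]),
    b_star = 200 * (f[2] - f[3]))
}

#' CIELAB spectral features of a cube (the 3-variable "CIELAB" set)
#'
#' Takes the ROI-mean reflectance of the three mapped bands as a linear RGB
#' triple, converts to XYZ then to CIELAB. Computing Lab on ROI means (not
#' per pixel) yields exactly three features per cube; per-pixel conversion
#' followed by averaging is available via `per_pixel = TRUE`.
#'
#' @param cube a calibrated [msi_cube()].
#' @param roi an [roi_mask()] or `NULL`.
#' @param mapping an [rgb_mapping()].
#' @param white_point reference white; defaults to [default_white_point()].
#' @param per_pixel convert each pixel to Lab and then average, instead of
#'   converting the ROI means.
#' @return Named numeric triple `(L_star, a_star, b_star)`.
#' @export
cielab_features <- function(cube, roi = NULL, mapping = rgb_mapping(),
                            white_point = default_white_point(),
                            per_pixel = FALSE) {
  stopifnot(inherits(cube, "msi_cube"), inherits(mapping, "rgb_mapping"))
  if (!cube$is_calibrated) stop("cielab_features requires a calibrated cube")
  want <- c(mapping$r_band_nm, mapping$g_band_nm, mapping$b_band_nm)
  idx <- match(want, cube$band_centers_nm)
  if (anyNA(idx)) {
    stop("mapping references band(s) absent from the cube: ",
         paste(want[is.na(idx)], collapse = ", "), " nm")
  }
  d <- dim(cube$pixels)
  mask <- if (is.null(roi)) matrix(TRUE, d[1], d[2]) else roi$mask
  if (!any(mask)) stop("empty ROI")
  if (per_pixel) {
    rgb <- vapply(idx, function(b) cube$pixels[, , b][mask],
                  numeric(sum(mask)))
    lab <- t(apply(rgb, 1, function(p) xyz_to_lab(rgb_to_xyz(p), white_point)))
    out <- colMeans(lab)
    names(out) <- c("L_star", "a_star", "b_star")
    out
  } else {
    means <- vapply(idx, function(b) mean(cube$pixels[, , b][mask]),
                    numeric(1))
    xyz_to_lab(rgb_to_xyz(means), white_point)
  }
}
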