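#' White/dark reference pair
#'
#' Flat-field references for reflectance calibration: `white` is the raw
#' response to a diffuse white standard, `dark` the shutter-closed counts.
#' Either full-frame 3-D arrays matching the raw cube, or `cols x bands`
#' matrices that broadcast down the scan (push-broom cameras record one
#' reference line per column).
#'
#' @param white,dark Numeric arrays of identical shape: `[row, col, band]` or
#'   `[col, band]`.
#' @return An object of class `hsi_refpair`.
#' @export
ref_pair <- function(white, dark) {
  white <- as.array(white)
  dark <- as.array(dark)
  if (!identical(dim(white), dim(dark))) {
    stop("`white` and `dark` must have identical shape", call. = FALSE)
  }
  nd <- length(dim(white))
  if (!nd %in% c(2L, 3L)) {
    stop("references must be [col, band] matrices or [row, col, band] arrays",
      call. = FALSE
    )
  }
  structure(list(white = white, dark = dark), class = "hsi_refpair")
}

expand_ref <- function(ref, d) {
  if (length(dim(ref)) == 3L) {
    if (!identical(dim(ref), d)) {
      stop("3-D reference shape does not match the raw cube", call. = FALSE)
    }
    return(ref)
  }
  if (!identical(dim(ref), d[2:3])) {
    stop("2-D reference must be [col, band] matching the raw cube", call. = FALSE)
  }
  # broadcast one reference line over every scanned row
  aperm(array(ref, c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Calibrate raw counts to reflectance
#'
#' Flat-field normalization against white and dark reference images:
#' \deqn{R = (raw - dark) / (white - dark).}
#' Reflectance is clipped to `[0, 1.5]`; out-of-range values and positions
#' where `white <= dark` (degenerate denominator) are flagged rather than
#' propagated as NaN: a pixel with any degenerate band is recorded in
#' `meta$invalid_px` and its value set to `NA`.
#'
#' @param raw An uncalibrated [hsi_cube] of sensor counts.
#' @param refs An [ref_pair].
#' @param clip Two-element numeric, the retained reflectance range.
#' @return A calibrated [hsi_cube] (`meta$calibrated = TRUE`) with
#'   `meta$invalid_px` a logical `row x col` matrix (TRUE = unusable pixel)
#'   and `meta$n_clipped` the count of clipped values.
#' @export
calibrate_reflectance <- function(raw, refs, clip = c(0, 1.5)) {
  stopifnot_cube(raw, "raw")
  if (!inherits(refs, "hsi_refpair")) stop("`refs` must be a ref_pair", call. = FALSE)
  if (isTRUE(raw$meta$calibrated)) {
    stop("`raw` is already calibrated", call. = FALSE)
  }
  d <- dim(raw$values)
  white <- expand_ref(refs$white, d)
  dark <- expand_ref(refs$dark, d)
  denom <- white - dark
  bad <- denom <= 0
  denom[bad] <- 1 # placeholder; flagged below
  r <- (raw$values - dark) / denom
  n_clipped <- sum(r < clip[1] | r > clip[2], na.rm = TRUE)
  r[r < clip[1]] <- clip[1]
  r[r > clip[2]] <- clip[2]
  invalid_px <- apply(bad, c(1, 2), any)
  if (any(invalid_px)) {
    r[array(rep(invalid_px, d[3]), d)] <- NA_real_
  }
  out <- hsi_cube(r, raw$wavelengths, raw$meta)
  out$meta$calibrated <- TRUE
  out$meta$invalid_px <- invalid_px
  out$meta$n_clipped <- n_clipped
  out
}

#' Convert reflectance to absorbance
#'
#' `A = -log10(max(R, floor))`. Layered tissue contributions add
#' approximately linearly in absorbance (Beer-Lambert), which is the
#' representation the classifier consumes. The floor caps the absorbance of
#' near-zero reflectance (shadow) pixels, which the highlight/shadow mask
#' removes anyway.
#'
#' @param cube A calibrated reflectance [hsi_cube].
#' @param floor Small positive reflectance floor (default `1e-4`, i.e.
#'   absorbance capped at 4).
#' @return An absorbance [hsi_cube] (`meta$absorbance = TRUE`).
#' @export
to_absorbance <- function(cube, floor = 1e-4) {
  stopifnot_cube(cube)
  if (!isTRUE(cube$meta$calibrated)) {
    stop("`cube` must be calibrated to reflectance before absorbance conversion",
      call. = FALSE
    )
  }
  if (isTRUE(cube$meta$absorbance)) {
    stop("`cube` is already in absorbance", call. = FALSE)
  }
  stopifnot(floor > 0)
  a <- -log10(pmax(cube$values, floor))
  out <- hsi_cube(a, cube$wavelengths, cube$meta)
  out$meta$absorbance <- TRUE
  out$meta$absorbance_floor <- floor
  out
}

#' Index of the band nearest a target wavelength
#'
#' Nominal wavelengths such as 1300 nm rarely fall exactly on the
#' instrument's 6.3 nm grid; this resolves them to the closest band center.
#' Ties go to the lower index.
#'
#' @param cube An [hsi_cube].
#' @param target_nm Target wavelength in nm.
#' @return 1-based band index.
#' @export
nearest_band <- function(cube, target_nm) {
  stopifnot_cube(cube)
  which.min(abs(cube$wavelengths - target_nm))
}

#' Pseudo-color rendering of a cube
#'
#' Maps three bands to RGB; the defaults (R: 1065 nm, G: 1280 nm,
#' B: 1981 nm) give the NIR false-color view used to present specimens.
#' Each channel is the nearest band's reflectance min-max rescaled to
#' `[0, 1]` over valid pixels; a constant channel rescales to all zeros.
#'
#' @param cube A calibrated [hsi_cube].
#' @param rgb_nm Wavelengths (nm) for the R, G and B channels.
#' @return An `rgb_image`: numeric array `[row, col, 3]` in `[0, 1]`.
#' @export
pseudo_color <- function(cube, rgb_nm = c(1065, 1280, 1981)) {
  stopifnot_cube(cube)
  if (!isTRUE(cube$meta$calibrated)) {
    stop("`cube` must be calibrated before rendering", call. = FALSE)
  }
  rng <- range(cube$wavelengths)
  outside <- rgb_nm < rng[1] | rgb_nm > rng[2]
  if (any(outside)) {
    stop(sprintf(
      "requested wavelength(s) %s nm outside cube range %.1f-%.1f nm",
      paste(rgb_nm[outside], collapse = ", "), rng[1], rng[2]
    ), call. = FALSE)
  }
  d <- dim(cube$values)
  img <- array(0, c(d[1], d[2], 3L))
  for (ch in 1:3) {
    plane <- cube$values[, , nearest_band(cube, rgb_nm[ch]), drop = TRUE]
    plane <- matrix(plane, d[1], d[2])
    lo <- min(plane, na.rm = TRUE)
    hi <- max(plane, na.rm = TRUE)
    scaled <- if (hi > lo) (plane - lo) / (hi - lo) else matrix(0, d[1], d[2])
    scaled[is.na(scaled)] <- 0
    img[, , ch] <- scaled
  }
  structure(img, class = "rgb_image", channels_nm = rgb_nm)
}
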