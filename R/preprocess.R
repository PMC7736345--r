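#' Pixel retention mask
#'
#' A logical `row x col` grid (`TRUE` = pixel retained) plus the ordered
#' list of rules that produced it. Masks compose by logical AND via
#' [mask_and()].
#'
#' @param values Logical matrix, `TRUE` = retained.
#' @param provenance List (or character vector) of rule descriptions.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(values, provenance = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  structure(list(values = values, provenance = as.list(provenance)),
    class = "pixel_mask"
  )
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf(
    "<pixel_mask> %d x %d, %d retained (%.1f%%); rules: %s\n",
    nrow(x$values), ncol(x$values), sum(x$values),
    100 * mean(x$values),
    if (length(x$provenance)) {
      paste(vapply(x$provenance, as.character, ""), collapse = " & ")
    } else {
      "<none>"
    }
  ))
  invisible(x)
}

#' Combine pixel masks by logical AND
#'
#' @param ... `pixel_mask` objects of identical shape.
#' @return A `pixel_mask` retaining pixels kept by every input; provenance
#'   is the concatenation of the inputs' rule lists.
#' @export
mask_and <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1L)
  v <- masks[[1]]$values
  prov <- masks[[1]]$provenance
  for (m in masks[-1]) {
    if (!identical(dim(m$values), dim(v))) {
      stop("masks must share a spatial shape", call. = FALSE)
    }
    v <- v & m$values
    prov <- c(prov, m$provenance)
  }
  pixel_mask(v, prov)
}

#' Restrict a cube to an analysis wavelength range
#'
#' Detector sensitivity drops and water absorption dominates above 1600 nm,
#' so bands beyond that are removed before classification.
#'
#' @param cube An [hsi_cube].
#' @param max_nm Retain bands with wavelength `<= max_nm` (default 1600).
#' @return An [hsi_cube] with the surviving bands, order preserved.
#' @export
select_bands <- function(cube, max_nm = 1600) {
  stopifnot_cube(cube)
  keep <- cube$wavelengths <= max_nm
  if (!any(keep)) {
    stop(sprintf(
      "no band survives selection: first wavelength %.1f nm > max_nm %.1f nm",
      cube$wavelengths[1], max_nm
    ), call. = FALSE)
  }
  if (all(keep)) {
    return(cube)
  }
  out <- hsi_cube(
    cube$values[, , keep, drop = FALSE],
    cube$wavelengths[keep],
    cube$meta
  )
  out$meta$band_selection_max_nm <- max_nm
  out
}

#' Mask specular highlights and shadows
#'
#' Probes the reflectance at 1300 nm: pixels with reflectance over `hi`
#' (default 70%) are specular highlights, below `lo` (default 10%) are
#' shadows; both carry no usable tissue spectrum and are removed. Thresholds
#' are inclusive-retain: a pixel at exactly 0.70 or 0.10 is kept.
#'
#' @param cube A calibrated reflectance [hsi_cube].
#' @param probe_nm Probe wavelength in nm (default 1300; resolved via
#'   [nearest_band()]).
#' @param hi,lo Reflectance thresholds as fractions.
#' @return A [pixel_mask]; pixels flagged invalid at calibration are also
#'   dropped.
#' @export
highlight_shadow_mask <- function(cube, probe_nm = 1300, hi = 0.70, lo = 0.10) {
  stopifnot_cube(cube)
  if (!isTRUE(cube$meta$calibrated) || isTRUE(cube$meta$absorbance)) {
    stop("highlight/shadow masking probes a calibrated reflectance cube",
      call. = FALSE
    )
  }
  rng <- range(cube$wavelengths)
  if (probe_nm < rng[1] || probe_nm > rng[2]) {
    stop(sprintf(
      "probe wavelength %.1f nm outside cube range %.1f-%.1f nm",
      probe_nm, rng[1], rng[2]
    ), call. = FALSE)
  }
  d <- dim(cube$values)
  plane <- matrix(cube$values[, , nearest_band(cube, probe_nm)], d[1], d[2])
  keep <- !is.na(plane) & plane >= lo & plane <= hi
  if (!is.null(cube$meta$invalid_px)) keep <- keep & !cube$meta$invalid_px
  pixel_mask(keep, sprintf(
    "highlight/shadow: retain %.2f <= R(%g nm) <= %.2f", lo, probe_nm, hi
  ))
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization `z = (x - mean(x)) / std(x)`: removes the
#' multiplicative scatter and additive baseline offsets that dominate
#' pixel-to-pixel variance in NIR reflectance measurements. `std` is the
#' population standard deviation (divide by `n`), the SNV convention; the
#' sample version differs only by a per-spectrum constant factor.
#'
#' @param x Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param tol Spectra with standard deviation `<= tol` are degenerate.
#' @return Transformed vector or matrix; every spectrum has mean 0 and
#'   (population) standard deviation 1.
#' @export
#' @examples
#' snv(c(1, 2, 3))
snv <- function(x, sd_type = c("population", "sample"), tol = 1e-12) {
  sd_type <- match.arg(sd_type)
  if (is.matrix(x)) {
    n <- ncol(x)
    if (n < 2L) stop("spectra must have length >= 2", call. = FALSE)
    mu <- rowMeans(x)
    centered <- x - mu
    denom_n <- if (sd_type == "population") n else n - 1L
    s <- sqrt(rowSums(centered^2) / denom_n)
    bad <- which(!(s > tol))
    if (length(bad)) {
      stop(sprintf(
        "constant spectrum (std <= %g) at row(s): %s",
        tol, paste(utils::head(bad, 5L), collapse = ", ")
      ), call. = FALSE)
    }
    return(centered / s)
  }
  n <- length(x)
  if (n < 2L) stop("spectra must have length >= 2", call. = FALSE)
  centered <- x - mean(x)
  denom_n <- if (sd_type == "population") n else n - 1L
  s <- sqrt(sum(centered^2) / denom_n)
  if (!(s > tol)) {
    stop(sprintf("constant spectrum (std <= %g)", tol), call. = FALSE)
  }
  centered / s
}

#' Per-pixel feature matrix
#'
#' One preprocessed spectrum per retained pixel, with the pixel coordinates
#' and the retained band centers. Built by [preprocess_cube()].
#'
#' @param X Numeric matrix, one spectrum per row.
#' @param pixel_index Tibble with `row`, `col` per matrix row.
#' @param wavelengths Band centers (nm) for the columns of `X`.
#' @return Object of class `hsi_features`.
#' @export
hsi_features <- function(X, pixel_index, wavelengths) {
  stopifnot(nrow(X) == nrow(pixel_index), ncol(X) == length(wavelengths))
  structure(
    list(
      X = X,
      pixel_index = tibble::as_tibble(pixel_index),
      wavelengths = as.numeric(wavelengths)
    ),
    class = "hsi_features"
  )
}

#' @export
print.hsi_features <- function(x, ...) {
  cat(sprintf(
    "<hsi_features> %d pixels x %d bands (%.1f-%.1f nm)\n",
    nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)
  ))
  invisible(x)
}

#' Preprocess a cube into classifier features
#'
#' The spectral pipeline feeding the SVM: absorbance conversion, band
#' selection to the analysis range, then row-wise SNV over the retained
#' pixels. Rows are emitted in row-major pixel order (row, then column).
#'
#' @param cube A calibrated reflectance [hsi_cube].
#' @param mask A [pixel_mask] of retained pixels (same spatial shape).
#' @param max_nm Band-selection cutoff in nm.
#' @param floor Reflectance floor for the absorbance transform.
#' @param space `"absorbance"` (default) or `"reflectance"`: representation
#'   fed to SNV.
#' @param sd_type Passed to [snv()].
#' @return An [hsi_features] matrix; every row has mean 0 and unit
#'   (population) standard deviation.
#' @export
preprocess_cube <- function(cube, mask, max_nm = 1600, floor = 1e-4,
                            space = c("absorbance", "reflectance"),
                            sd_type = "population") {
  stopifnot_cube(cube)
  space <- match.arg(space)
  d <- dim(cube$values)
  if (!identical(dim(mask$values), d[1:2])) {
    stop("mask shape does not match cube spatial shape", call. = FALSE)
  }
  work <- if (space == "absorbance") to_absorbance(cube, floor) else cube
  work <- select_bands(work, max_nm)

  keep <- which(t(mask$values)) # row-major order over (row, col)
  if (!length(keep)) stop("zero retained pixels", call. = FALSE)
  nb <- dim(work$values)[3]
  flat <- matrix(aperm(work$values, c(2, 1, 3)), d[1] * d[2], nb)
  X <- flat[keep, , drop = FALSE]
  if (anyNA(X)) stop("retained pixels contain NA values; mask out invalid pixels",
    call. = FALSE
  )
  idx0 <- keep - 1L
  pixel_index <- tibble::tibble(
    row = idx0 %/% d[2] + 1L,
    col = idx0 %% d[2] + 1L
  )
  hsi_features(snv(X, sd_type = sd_type), pixel_index, work$wavelengths)
}
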