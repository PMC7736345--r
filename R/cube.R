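#' Hyperspectral data cube
#'
#' A push-broom NIR hyperspectral scan is a 3-D "data cube": a full
#' reflectance (or absorbance) spectrum at every spatial pixel. `hsi_cube()`
#' wraps the numeric array together with its wavelength axis and free-form
#' provenance metadata.
#'
#' @param values Numeric 3-D array indexed `[row, col, band]`. Calibrated
#'   cubes hold unitless reflectance in `[0, 1]` (values up to 1.5 are kept
#'   but flagged); raw cubes hold sensor counts.
#' @param wavelengths Strictly increasing numeric vector of band centers in
#'   nanometres; its length must equal `dim(values)[3]`.
#' @param meta Named list of provenance entries (specimen id, calibration
#'   state, source path, ...). `meta$calibrated` and `meta$absorbance` are
#'   interpreted by downstream steps.
#'
#' @return An object of class `hsi_cube`.
#' @seealso [read_cube()], [calibrate_reflectance()], [pseudo_color()]
#' @export
#' @examples
#' cube <- hsi_cube(array(runif(4 * 4 * 3), c(4, 4, 3)), c(1000, 1006.3, 1012.6))
#' cube
hsi_cube <- function(values, wavelengths, meta = list()) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array [row, col, band]", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L]) {
    stop(sprintf(
      "wavelength count (%d) does not match band axis extent (%d)",
      length(wavelengths), dim(values)[3L]
    ), call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(values = values, wavelengths = wavelengths, meta = as.list(meta)),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  state <- if (isTRUE(x$meta$absorbance)) {
    "absorbance"
  } else if (isTRUE(x$meta$calibrated)) {
    "reflectance"
  } else {
    "raw counts"
  }
  cat(sprintf(
    "<hsi_cube> %d x %d px, %d bands (%.1f-%.1f nm), %s\n",
    d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), state
  ))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

is_hsi_cube <- function(x) inherits(x, "hsi_cube")

stopifnot_cube <- function(x, arg = "cube") {
  if (!is_hsi_cube(x)) stop(sprintf("`%s` must be an hsi_cube", arg), call. = FALSE)
  invisible(x)
}

cube_spatial_dim <- function(cube) dim(cube$values)[1:2]

# ---- ENVI I/O ---------------------------------------------------------------
# ENVI stores a text .hdr next to a raw binary file. Required header keys:
# samples (cols), lines (rows), bands, data type, interleave, wavelength.
# Only little-endian (byte order 0) files are handled; data types 4 (float32)
# and 5 (float64) are supported, which covers calibrated reflectance data.

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  fields <- list()
  # values are either scalar ("key = value") or brace-enclosed lists
  pat <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n{]*)", txt, perl = TRUE)
  m <- regmatches(txt, pat)[[1]]
  for (entry in m) {
    key <- trimws(sub("=.*$", "", entry))
    val <- trimws(sub("^[^=]*=", "", entry))
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_field_num <- function(fields, key, path) {
  if (is.null(fields[[key]])) {
    stop(sprintf("ENVI header %s is missing required field '%s'", path, key),
      call. = FALSE
    )
  }
  as.numeric(fields[[key]])
}

read_envi_cube <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  dat_path <- sub("\\.hdr$", "", hdr_path)
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path, call. = FALSE)
  if (!file.exists(dat_path)) stop("ENVI data file not found: ", dat_path, call. = FALSE)
  fields <- parse_envi_header(hdr_path)

  samples <- envi_field_num(fields, "samples", hdr_path)
  lines <- envi_field_num(fields, "lines", hdr_path)
  bands <- envi_field_num(fields, "bands", hdr_path)
  dtype <- envi_field_num(fields, "data type", hdr_path)
  interleave <- tolower(trimws(fields[["interleave"]] %||% "bsq"))
  byte_order <- as.numeric(fields[["byte order"]] %||% "0")
  if (byte_order != 0) stop("only little-endian ENVI files are supported", call. = FALSE)
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported ENVI interleave: ", interleave, call. = FALSE)
  }
  size <- switch(as.character(dtype),
    "4" = 4L,
    "5" = 8L,
    stop("unsupported ENVI data type: ", dtype, " (expect 4 or 5)", call. = FALSE)
  )

  wl_raw <- fields[["wavelength"]]
  if (is.null(wl_raw)) {
    stop(sprintf("ENVI header %s is missing required field 'wavelength'", hdr_path),
      call. = FALSE
    )
  }
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl_raw), ",")[[1]])
  wl <- wl[!is.na(wl)]
  if (length(wl) != bands) {
    stop(sprintf(
      "ENVI header declares %d bands but lists %d wavelengths", bands, length(wl)
    ), call. = FALSE)
  }

  n <- samples * lines * bands
  raw <- readBin(dat_path, what = "numeric", n = n, size = size, endian = "little")
  if (length(raw) != n) {
    stop("ENVI data file shorter than header-declared extent", call. = FALSE)
  }
  # fastest-varying axis first, per interleave; rows are ENVI "lines",
  # cols are "samples"
  values <- switch(interleave,
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw, c(bands, samples, lines)), c(3, 2, 1))
  )
  hsi_cube(values, wl, meta = list(source = dat_path, format = "envi"))
}

write_envi_cube <- function(cube, path, interleave = "bsq") {
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  dat_path <- sub("\\.hdr$", "", hdr_path)
  d <- dim(cube$values)
  flat <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1))
  )
  hdr <- c(
    "ENVI",
    "description = { nirgist hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf(
      "wavelength = {\n%s }",
      paste(format(cube$wavelengths, trim = TRUE, digits = 12), collapse = ",\n")
    )
  )
  writeLines(hdr, hdr_path)
  writeBin(as.numeric(flat), dat_path, size = 8L, endian = "little")
  invisible(dat_path)
}

#' Read a hyperspectral cube
#'
#' Reads either an ENVI file pair (text `.hdr` header plus raw binary, with
#' `bsq`/`bil`/`bip` interleaves) or the package's portable single-file RDS
#' container.
#'
#' @param path Path to the ENVI header (or its data file) or to an `.rds`
#'   container written by [write_cube()].
#' @param format `"auto"` (by extension), `"envi"` or `"rds"`.
#' @return An [hsi_cube] with its wavelength axis populated; `meta` records
#'   the source path and format.
#' @export
read_cube <- function(path, format = c("auto", "envi", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  }
  if (format == "envi") {
    return(read_envi_cube(path))
  }
  obj <- readRDS(path)
  cube <- hsi_cube(obj$values, obj$wavelengths, obj$meta %||% list())
  cube$meta$source <- path
  cube$meta$format <- "rds"
  cube
}

#' Write a hyperspectral cube
#'
#' @param cube An [hsi_cube].
#' @param path Output path (`.hdr` for ENVI, `.rds` for the portable
#'   container).
#' @param format `"auto"`, `"envi"` or `"rds"`.
#' @param interleave ENVI band interleave to write (`"bsq"`, `"bil"`,
#'   `"bip"`).
#' @return The data-file path, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "rds"),
                       interleave = "bsq") {
  stopifnot_cube(cube)
  if (any(dim(cube$values)[1:2] == 0L)) {
    stop("refusing to write a cube with an empty spatial extent", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
  }
  if (format == "envi") {
    return(invisible(write_envi_cube(cube, path, interleave)))
  }
  saveRDS(
    list(values = cube$values, wavelengths = cube$wavelengths, meta = cube$meta),
    path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
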