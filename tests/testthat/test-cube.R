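test_that("write/read round-trips are the identity for every format and interleave", {
  cube <- toy_cube(5, 3, 8)
  for (fmt in list(
    list(format = "envi", interleave = "bsq", ext = ".hdr"),
    list(format = "envi", interleave = "bil", ext = ".hdr"),
    list(format = "envi", interleave = "bip", ext = ".hdr"),
    list(format = "rds", interleave = "bsq", ext = ".rds")
  )) {
    path <- withr::local_tempfile(fileext = fmt$ext)
    write_cube(cube, path, format = fmt$format, interleave = fmt$interleave)
    back <- read_cube(path, format = fmt$format)
    expect_identical(back$values, cube$values)
    expect_identical(back$wavelengths, cube$wavelengths)
  }
})

test_that("an ENVI header on the instrument grid yields the 215-band wavelength axis", {
  cube <- toy_cube(2, 2, 215)
  path <- withr::local_tempfile(fileext = ".hdr")
  write_cube(cube, path, format = "envi")
  back <- read_cube(path)
  expect_length(back$wavelengths, 215)
  expect_equal(back$wavelengths[1], 1000)
  expect_equal(back$wavelengths[215], 2348.2)
  expect_equal(diff(back$wavelengths), rep(6.3, 214))
})

test_that("contradictory or incomplete ENVI headers are rejected", {
  cube <- toy_cube(2, 2, 10)
  path <- withr::local_tempfile(fileext = ".hdr")
  write_cube(cube, path, format = "envi")
  hdr <- readLines(path)
  # drop one wavelength: header says 10 bands, lists 9
  wl_start <- grep("^wavelength", hdr)
  broken <- hdr[-(wl_start + 1L)]
  writeLines(broken, path)
  expect_error(read_cube(path), "10 bands but lists 9")

  writeLines(hdr[!grepl("^samples", hdr)], path)
  expect_error(read_cube(path), "missing required field 'samples'")
})

test_that("cube invariants are enforced at construction", {
  expect_error(hsi_cube(array(0, c(2, 2, 3)), c(1, 2)), "does not match")
  expect_error(hsi_cube(array(0, c(2, 2, 3)), c(3, 2, 1)), "strictly increasing")
  expect_error(
    write_cube(hsi_cube(array(0, c(0, 0, 3)), 1:3), tempfile(fileext = ".rds")),
    "empty spatial extent"
  )
})

test_that("reflectance calibration anchors raw counts at the references", {
  nb <- 6
  wl <- default_wavelengths(nb)
  white <- array(4000, c(3, 3, nb))
  dark <- array(400, c(3, 3, nb))
  refs <- ref_pair(white, dark)
  raw_at <- function(frac) hsi_cube(dark + frac * (white - dark), wl)

  expect_equal(unname(calibrate_reflectance(raw_at(0), refs)$values[2, 2, 3]), 0)
  expect_equal(unname(calibrate_reflectance(raw_at(1), refs)$values[2, 2, 3]), 1)
  expect_equal(unname(calibrate_reflectance(raw_at(0.5), refs)$values[2, 2, 3]), 0.5)
  expect_true(isTRUE(calibrate_reflectance(raw_at(0.5), refs)$meta$calibrated))
})

test_that("calibration is invariant to a common positive gain on all counts", {
  nb <- 4
  set.seed(1)
  white <- array(runif(12 * nb, 3000, 5000), c(3, 4, nb))
  dark <- array(runif(12 * nb, 100, 300), c(3, 4, nb))
  raw <- dark + array(runif(12 * nb, 0, 1), c(3, 4, nb)) * (white - dark)
  r1 <- calibrate_reflectance(hsi_cube(raw, default_wavelengths(nb)), ref_pair(white, dark))
  r2 <- calibrate_reflectance(
    hsi_cube(raw * 7.5, default_wavelengths(nb)),
    ref_pair(white * 7.5, dark * 7.5)
  )
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("degenerate white == dark positions are flagged, not NaN-propagated", {
  nb <- 4
  white <- array(4000, c(2, 2, nb))
  dark <- array(400, c(2, 2, nb))
  white[1, 1, 2] <- 400 # degenerate at one band of pixel (1,1)
  raw <- hsi_cube(array(2000, c(2, 2, nb)), default_wavelengths(nb))
  cal <- calibrate_reflectance(raw, ref_pair(white, dark))
  expect_true(cal$meta$invalid_px[1, 1])
  expect_false(any(cal$meta$invalid_px[-1, ]))
  expect_true(all(is.na(cal$values[1, 1, ])))
  expect_false(anyNA(cal$values[2, , ]))
})

test_that("per-scanline (col x band) references broadcast over rows", {
  nb <- 3
  white <- matrix(4000, 4, nb) # cols x bands
  dark <- matrix(400, 4, nb)
  raw <- hsi_cube(array(2200, c(5, 4, nb)), default_wavelengths(nb))
  cal <- calibrate_reflectance(raw, ref_pair(white, dark))
  expect_equal(unname(cal$values[3, 2, 1]), (2200 - 400) / 3600)
})

test_that("absorbance transform follows -log10 with a reflectance floor", {
  nb <- 3
  mk <- function(r) {
    hsi_cube(array(r, c(1, 1, nb)), default_wavelengths(nb),
      meta = list(calibrated = TRUE)
    )
  }
  expect_equal(unname(to_absorbance(mk(1))$values[1, 1, 1]), 0)
  expect_equal(unname(to_absorbance(mk(0.1))$values[1, 1, 1]), 1)
  expect_equal(unname(to_absorbance(mk(0), floor = 1e-4)$values[1, 1, 1]), 4)
  uncal <- hsi_cube(array(0.5, c(1, 1, nb)), default_wavelengths(nb))
  expect_error(to_absorbance(uncal), "calibrated")
})

test_that("nearest_band resolves off-grid targets and breaks ties downward", {
  cube <- toy_cube(1, 1, 215)
  # 1300 nm sits between 1296.1 and 1302.4; 1302.4 is closer
  expect_equal(nearest_band(cube, 1300), 49L)
  expect_equal(cube$wavelengths[nearest_band(cube, 1300)], 1302.4)
  # every grid wavelength resolves to itself
  idx <- vapply(cube$wavelengths, function(w) nearest_band(cube, w), 1L)
  expect_equal(idx, seq_len(215))
  # exact midpoint -> lower index
  mid <- (cube$wavelengths[10] + cube$wavelengths[11]) / 2
  expect_equal(nearest_band(cube, mid), 10L)
})

test_that("pseudo-color rendering rescales the default NIR bands into [0,1]", {
  cube <- toy_cube(6, 5, 215)
  img <- pseudo_color(cube)
  expect_s3_class(img, "rgb_image")
  expect_equal(dim(img), c(6L, 5L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(attr(img, "channels_nm"), c(1065, 1280, 1981))

  # channel equals the min-max rescaled nearest band
  b <- nearest_band(cube, 1065)
  plane <- cube$values[, , b]
  expect_equal(img[, , 1], (plane - min(plane)) / (max(plane) - min(plane)))

  # degenerate rescale: constant cube -> all zeros
  const <- toy_cube(3, 3, 215, fill = 0.4)
  expect_true(all(pseudo_color(const) == 0))

  # single pixel
  one <- toy_cube(1, 1, 215)
  expect_equal(dim(pseudo_color(one)), c(1L, 1L, 3L))

  # out-of-range request names the range
  desk <- toy_cube(2, 2, 96)
  expect_error(pseudo_color(desk), "1981")
})
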