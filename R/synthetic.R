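#' Instrument wavelength grid
#'
#' Band centers of the push-broom NIR camera: 6.3 nm steps from 1000 nm.
#' The full instrument grid has 215 bands (1000-2348.2 nm); the desk-scale
#' default keeps the 96 analysis bands at or below 1600 nm.
#'
#' @param n_bands Number of bands (96 desk-scale, 215 full instrument).
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function(n_bands = 96) {
  1000 + 6.3 * (seq_len(n_bands) - 1)
}

gaussian_band <- function(wl, center, width) {
  exp(-((wl - center)^2) / (2 * width^2))
}

#' Synthetic tissue endmembers
#'
#' Smooth per-tissue absorptivity curves (unitless absorbance per mm of
#' tissue path) built from sums of Gaussian bands: a mucosa/normal curve
#' with the water-absorption bump near 1450 nm, a GIST curve that is the
#' mucosa curve plus a smooth seeded perturbation, and a flat-ish stage
#' background curve. The GIST/normal contrast is controlled by
#' `separation`: the L2 distance between the two curves after SNV, matched
#' by root finding to within 0.1%. The real tissues' spectra are described
#' as similar in shape, so the default separation is small relative to the
#' SNV-spectrum norm (`sqrt(n_bands)`, about 9.8 at 96 bands).
#'
#' @param seed Integer seed for the perturbation shape.
#' @param separation Target post-SNV L2 distance `delta >= 0` between the
#'   gist and normal curves.
#' @param wavelengths Band grid in nm.
#' @return Object of class `endmember_set` with fields `wavelengths`,
#'   `normal`, `gist`, `background`, `separation`, `seed`.
#' @export
make_endmembers <- function(seed = 1L, separation = 1.5,
                            wavelengths = default_wavelengths()) {
  stopifnot(separation >= 0)
  wl <- wavelengths
  normal <- 0.10 +
    0.06 * gaussian_band(wl, 1200, 80) +
    0.10 * gaussian_band(wl, 1450, 60) +
    0.03 * gaussian_band(wl, 1050, 50)

  if (separation == 0) {
    gist <- normal
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    centers <- stats::runif(3, min(wl) + 50, max(wl) - 50)
    widths <- stats::runif(3, 40, 90)
    amps <- stats::runif(3, -1, 1)
    pert <- rowSums(vapply(
      1:3, function(j) amps[j] * gaussian_band(wl, centers[j], widths[j]),
      numeric(length(wl))
    ))
    pert <- pert - mean(pert)
    if (sqrt(sum(pert^2)) < 1e-8) pert <- gaussian_band(wl, 1250, 60) - 0.2
    snv_dist <- function(s) {
      sqrt(sum((snv(normal + s * pert) - snv(normal))^2)) - separation
    }
    upper <- 0.05
    while (snv_dist(upper) < 0 && upper < 1e4) upper <- upper * 2
    if (snv_dist(upper) < 0) {
      stop("requested separation infeasible with this band count", call. = FALSE)
    }
    s <- stats::uniroot(snv_dist, c(0, upper), tol = 1e-10)$root
    gist <- normal + s * pert
    # SNV is offset-invariant, so lifting a dipping curve does not change
    # the realized separation
    if (min(gist) < 0.02) gist <- gist + (0.02 - min(gist))
  }
  background <- 0.30 + 0.02 * gaussian_band(wl, 1450, 120)
  structure(
    list(
      wavelengths = wl, normal = normal, gist = gist,
      background = background, separation = separation, seed = seed
    ),
    class = "endmember_set"
  )
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic specimen configuration
#'
#' Defaults emulate the study conditions at desk scale: 64 x 64 px cubes on
#' the 96-band analysis grid, a submucosal lesion whose covering mucosa is
#' 0.4-2.5 mm thick, multiplicative/additive scatter artifacts (removed by
#' SNV), sensor noise, planted highlight/shadow pixels, a freehand-jittered
#' boundary polyline of thickness 2 px, and auto-placed training boxes.
#'
#' @param shape Spatial grid `(rows, cols)`.
#' @param n_bands Number of bands on the 6.3 nm grid.
#' @param depth_range_mm Mucosa thickness range over the lesion (mm).
#' @param total_path_mm Range of the total sampled tissue path (mm), one
#'   smooth field shared by all tissue pixels; over the lesion it splits
#'   into mucosa cover plus GIST layer, so the total-absorbance
#'   distribution carries no class information and `separation = 0` is a
#'   true null.
#' @param noise_sd Additive Gaussian noise sd on absorbance.
#' @param gain_range,offset_range Per-pixel multiplicative gain and additive
#'   offset artifact ranges (uniform).
#' @param highlight_frac,shadow_frac Fractions of tissue pixels planted as
#'   specular highlights / shadows.
#' @param boundary_thickness_px Nominal drawn-line thickness `t` (px).
#' @param boundary_jitter_sd Radial freehand jitter sd of the boundary (px).
#' @param box_size Training-box side length (px).
#' @param n_normal_boxes Normal training boxes per mixed specimen.
#' @param artifacts Apply gain/offset artifacts (disable for twin cohorts).
#' @param include_raw Also emit the raw/white/dark calibration triplet.
#' @return Named list of class `specimen_config`.
#' @export
specimen_config <- function(shape = c(64, 64), n_bands = 96,
                            depth_range_mm = c(0.4, 2.5),
                            total_path_mm = c(3, 5),
                            noise_sd = 0.02,
                            gain_range = c(0.85, 1.15),
                            offset_range = c(-0.05, 0.05),
                            highlight_frac = 0.01, shadow_frac = 0.01,
                            boundary_thickness_px = 2,
                            boundary_jitter_sd = 0.8,
                            box_size = 8, n_normal_boxes = 2,
                            artifacts = TRUE, include_raw = FALSE) {
  if (total_path_mm[1] <= depth_range_mm[2]) {
    stop("total_path_mm must exceed the maximum mucosa depth", call. = FALSE)
  }
  structure(
    list(
      shape = shape, n_bands = n_bands, depth_range_mm = depth_range_mm,
      total_path_mm = total_path_mm,
      noise_sd = noise_sd, gain_range = gain_range,
      offset_range = offset_range, highlight_frac = highlight_frac,
      shadow_frac = shadow_frac,
      boundary_thickness_px = boundary_thickness_px,
      boundary_jitter_sd = boundary_jitter_sd,
      box_size = box_size, n_normal_boxes = n_normal_boxes,
      artifacts = artifacts, include_raw = include_raw
    ),
    class = "specimen_config"
  )
}

# smooth closed polygon: ellipse sampled at n vertices with smoothed radial
# jitter, emulating a freehand-drawn line
freehand_ellipse <- function(center, radii, n = 60, jitter_sd = 0.8) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  jit <- stats::rnorm(n, 0, jitter_sd)
  jit <- stats::filter(c(jit, jit, jit), rep(1 / 5, 5), circular = TRUE)[(n + 1):(2 * n)]
  r <- center[1] + (radii[1] + jit) * sin(theta)
  c <- center[2] + (radii[2] + jit) * cos(theta)
  v <- cbind(r, c)
  rbind(v, v[1, , drop = FALSE])
}

# deterministic raster scan for an axis-aligned box whose pixels all satisfy
# `ok` (logical matrix); returns c(r0, c0) or NULL
place_box <- function(ok, size, taken, step = 2L) {
  nr <- nrow(ok)
  nc <- ncol(ok)
  for (r0 in seq(1L, nr - size + 1L, by = step)) {
    for (c0 in seq(1L, nc - size + 1L, by = step)) {
      sub <- ok[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
      if (all(sub) && !any(taken[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])) {
        return(c(r0, c0))
      }
    }
  }
  NULL
}

#' Generate one synthetic specimen
#'
#' Builds a reflectance cube with the statistical structure the analysis
#' assumes: layered Beer-Lambert absorbance mixing
#' `A = d_mucosa * eps_mucosa + d_gist * eps_gist` over the lesion (normal
#' pixels carry mucosa/submucosa path only), per-pixel multiplicative gain
#' and additive offset artifacts, additive Gaussian noise, planted
#' highlight/shadow pixels, then `R = 10^-A`. Ground truth, a
#' freehand-jittered boundary polyline and auto-placed training boxes are
#' generated alongside.
#'
#' @param config A [specimen_config()].
#' @param seed Integer seed (all randomness flows from it).
#' @param endmembers An [make_endmembers()] set on the matching band grid.
#' @param gist_only If `TRUE` the whole specimen extent is lesion (no normal
#'   region, no normal boxes), emulating the all-GIST specimens.
#' @param id Specimen id string.
#' @return An `hsi_specimen` with extra fields `truth` (label image),
#'   `depth_map` (mm, positive only over the lesion), `seed`, `config`, and
#'   (if `include_raw`) `raw`, `refs`.
#' @export
make_specimen <- function(config = specimen_config(), seed = 1L,
                          endmembers = make_endmembers(
                            wavelengths = default_wavelengths(config$n_bands)
                          ),
                          gist_only = FALSE, id = "specimen") {
  stopifnot(inherits(config, "specimen_config"))
  wl <- endmembers$wavelengths
  if (length(wl) != config$n_bands) {
    stop("endmember grid does not match config$n_bands", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  nr <- config$shape[1]
  nc <- config$shape[2]
  nb <- config$n_bands
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  ext_radii <- 0.47 * c(nr, nc)

  if (gist_only) {
    les_center <- ctr
    les_radii <- stats::runif(2, 0.30, 0.38) * c(nr, nc)
  } else {
    # offset the lesion so a wide normal region remains for training boxes
    phi <- stats::runif(1, 0, 2 * pi)
    les_center <- ctr + 0.10 * min(nr, nc) * c(sin(phi), cos(phi))
    les_radii <- stats::runif(2, 0.22, 0.28) * c(nr, nc)
  }
  if (any(les_radii >= ext_radii)) {
    stop("lesion larger than the specimen extent", call. = FALSE)
  }
  boundary_v <- freehand_ellipse(les_center, les_radii,
    jitter_sd = config$boundary_jitter_sd
  )
  extent_v <- if (gist_only) {
    boundary_v
  } else {
    freehand_ellipse(ctr, ext_radii, n = 80, jitter_sd = 0.3)
  }

  ann0 <- annotation_set(
    boundary = list(vertices = boundary_v, thickness_px = config$boundary_thickness_px),
    boxes = tibble::tibble(
      label = character(), r0 = numeric(), c0 = numeric(),
      r1 = numeric(), c1 = numeric()
    ),
    extent = list(vertices = extent_v),
    validate = FALSE
  )
  truth <- rasterize_labels(ann0, c(nr, nc))
  excl <- exclusion_mask(ann0, c(nr, nc))

  # mucosa depth over the lesion: smooth tilted plane clipped to range
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- config$depth_range_mm
  base_d <- stats::runif(1, dr[1], dr[2])
  tilt <- stats::runif(2, -1, 1) * diff(dr) / 2
  depth <- base_d + tilt[1] * (rr - ctr[1]) / nr + tilt[2] * (cc - ctr[2]) / nc
  depth <- pmin(dr[2], pmax(dr[1], depth))
  depth_map <- ifelse(truth == 2L, depth, 0)

  # total sampled tissue path: one smooth field shared by all tissue pixels,
  # so total absorbance carries no class label information
  tp <- config$total_path_mm
  tp_base <- stats::runif(1, tp[1], tp[2])
  tp_tilt <- stats::runif(2, -1, 1) * diff(tp) / 2
  t_path <- tp_base + tp_tilt[1] * (rr - ctr[1]) / nr +
    tp_tilt[2] * (cc - ctr[2]) / nc
  t_path <- pmin(tp[2], pmax(tp[1], t_path))

  # layered Beer-Lambert mixing, vectorized: pixels x bands. Lesion pixels
  # split the path into mucosa cover + gist layer; normal pixels are
  # mucosa/submucosa throughout.
  n_px <- nr * nc
  is_gist <- as.vector(truth == 2L)
  is_norm <- as.vector(truth == 1L)
  d_gist <- pmax(as.vector(t_path) - as.vector(depth_map), 0)
  A <- matrix(0, n_px, nb)
  A[is_norm, ] <- as.vector(t_path)[is_norm] %o% endmembers$normal
  A[is_gist, ] <- as.vector(depth_map)[is_gist] %o% endmembers$normal +
    d_gist[is_gist] %o% endmembers$gist
  n_bg <- sum(!is_gist & !is_norm)
  A[!is_gist & !is_norm, ] <- matrix(endmembers$background, n_bg, nb, byrow = TRUE)

  # artifact fields are drawn unconditionally so that an artifact-free twin
  # generated from the same seed shares geometry, noise and planted pixels
  gain <- stats::runif(n_px, config$gain_range[1], config$gain_range[2])
  offs <- stats::runif(n_px, config$offset_range[1], config$offset_range[2])
  if (config$artifacts) {
    A <- A * gain + offs
  }
  if (config$noise_sd > 0) {
    A <- A + matrix(stats::rnorm(n_px * nb, 0, config$noise_sd), n_px, nb)
  }
  R <- 10^(-A)

  # planted highlight/shadow pixels within the tissue extent
  tissue_idx <- which(is_gist | is_norm)
  n_hi <- round(config$highlight_frac * length(tissue_idx))
  n_sh <- round(config$shadow_frac * length(tissue_idx))
  planted <- sample(tissue_idx, min(n_hi + n_sh, length(tissue_idx)))
  hi_px <- utils::head(planted, n_hi)
  sh_px <- utils::tail(planted, n_sh)
  if (length(hi_px)) R[hi_px, ] <- 0.85 + stats::rnorm(length(hi_px) * nb, 0, 0.01)
  if (length(sh_px)) R[sh_px, ] <- 0.04 + stats::rnorm(length(sh_px) * nb, 0, 0.005)
  R <- pmin(1.5, pmax(0, R))

  cube_vals <- array(R, c(nr, nc, nb)) # column-major matches matrix layout
  cube <- hsi_cube(cube_vals, wl, meta = list(
    calibrated = TRUE, specimen = id, seed = seed, synthetic = TRUE
  ))

  # training boxes: placement avoids the exclusion corridor by construction
  size <- config$box_size
  taken <- matrix(FALSE, nr, nc)
  ok_gist <- truth == 2L & excl$values
  pos <- place_box(ok_gist, size, taken)
  if (is.null(pos)) stop("could not place a gist training box", call. = FALSE)
  boxes <- tibble::tibble(
    label = "gist", r0 = pos[1], c0 = pos[2],
    r1 = pos[1] + size - 1, c1 = pos[2] + size - 1
  )
  taken[pos[1]:(pos[1] + size - 1), pos[2]:(pos[2] + size - 1)] <- TRUE
  if (!gist_only) {
    ok_norm <- truth == 1L & excl$values
    for (j in seq_len(config$n_normal_boxes)) {
      pos <- place_box(ok_norm, size, taken)
      if (is.null(pos)) stop("could not place a normal training box", call. = FALSE)
      boxes <- dplyr::bind_rows(boxes, tibble::tibble(
        label = "normal", r0 = pos[1], c0 = pos[2],
        r1 = pos[1] + size - 1, c1 = pos[2] + size - 1
      ))
      taken[pos[1]:(pos[1] + size - 1), pos[2]:(pos[2] + size - 1)] <- TRUE
    }
  }
  ann <- annotation_set(
    boundary = list(vertices = boundary_v, thickness_px = config$boundary_thickness_px),
    boxes = boxes,
    extent = list(vertices = extent_v),
    validate = TRUE
  )

  spec <- specimen_record(id, cube, ann)
  spec$truth <- truth
  spec$depth_map <- depth_map
  spec$seed <- seed
  spec$config <- config
  spec$gist_only <- gist_only
  if (config$include_raw) {
    white_curve <- 30000 * (0.7 + 0.3 * gaussian_band(wl, 1250, 400))
    white <- array(rep(white_curve, each = n_px), c(nr, nc, nb))
    dark <- array(800, c(nr, nc, nb))
    spec$refs <- ref_pair(white, dark)
    spec$raw <- hsi_cube(
      dark + cube_vals * (white - dark), wl,
      meta = list(specimen = id, synthetic = TRUE)
    )
  }
  spec
}

#' Cohort configuration
#'
#' @param specimen A [specimen_config()] template shared by all specimens.
#' @param separation Endmember post-SNV separation `delta`.
#' @param n_gist_only Number of specimens whose whole extent is lesion
#'   (default 5 of 12, matching the study's result table, where rows with
#'   only GIST regions report no FPR/specificity).
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(specimen = specimen_config(), separation = 1.5,
                          n_gist_only = 5) {
  structure(
    list(specimen = specimen, separation = separation, n_gist_only = n_gist_only),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' `n` specimens with independently drawn geometry, depth fields and noise;
#' the last `n_gist_only` are all-lesion specimens. All randomness flows
#' from `seed`, so the same call reproduces the cohort exactly.
#'
#' @param n Number of specimens (default 12, the study size).
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return List of `hsi_specimen`s (ids `"a"`, `"b"`, ...), with the shared
#'   `endmember_set` attached as attribute `endmembers`.
#' @export
make_cohort <- function(n = 12, config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n >= 2)
  if (config$n_gist_only > n - 2) {
    stop("need at least 2 mixed specimens for training folds", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  spec_seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  em <- make_endmembers(
    seed = spec_seeds[n + 1L], separation = config$separation,
    wavelengths = default_wavelengths(config$specimen$n_bands)
  )
  ids <- letters[seq_len(n)]
  gist_only <- seq_len(n) > n - config$n_gist_only
  cohort <- lapply(seq_len(n), function(i) {
    make_specimen(config$specimen,
      seed = spec_seeds[i], endmembers = em,
      gist_only = gist_only[i], id = ids[i]
    )
  })
  attr(cohort, "endmembers") <- em
  cohort
}

#' Write a cohort to disk
#'
#' Emits, per specimen, the reflectance cube (ENVI pair or portable RDS),
#' the annotation JSON and a truth label CSV, plus a cohort `manifest.json`
#' listing members, seeds and file checksums.
#'
#' @param cohort From [make_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"envi"` or `"rds"` cubes.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("envi", "rds")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (spec in cohort) {
    stem <- file.path(dir, spec$id)
    cube_path <- if (format == "envi") {
      write_cube(spec$cube, paste0(stem, ".hdr"), format = "envi")
      paste0(stem, ".hdr")
    } else {
      write_cube(spec$cube, paste0(stem, ".rds"), format = "rds")
      paste0(stem, ".rds")
    }
    ann_path <- paste0(stem, "_annotations.json")
    write_annotations(spec$annotations, ann_path)
    truth_path <- paste0(stem, "_truth.csv")
    utils::write.table(unclass(spec$truth), truth_path,
      sep = ",",
      row.names = FALSE, col.names = FALSE
    )
    files <- c(cube_path, ann_path, truth_path)
    if (format == "envi") files <- c(files, sub("\\.hdr$", "", cube_path))
    entries[[spec$id]] <- list(
      id = spec$id, seed = spec$seed, gist_only = isTRUE(spec$gist_only),
      files = stats::setNames(
        as.list(unname(tools::md5sum(files))), basename(files)
      )
    )
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n = length(cohort), members = unname(entries)),
    manifest,
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
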