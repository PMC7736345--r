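#' Specimen record
#'
#' Bundles one specimen's calibrated cube and annotations, the unit over
#' which leave-one-specimen-out folds are formed.
#'
#' @param id Specimen label.
#' @param cube A calibrated reflectance [hsi_cube].
#' @param annotations An [annotation_set].
#' @return Object of class `hsi_specimen`.
#' @export
specimen_record <- function(id, cube, annotations) {
  stopifnot_cube(cube)
  if (!inherits(annotations, "annotation_set")) {
    stop("`annotations` must be an annotation_set", call. = FALSE)
  }
  structure(
    list(id = as.character(id), cube = cube, annotations = annotations),
    class = "hsi_specimen"
  )
}

#' @export
print.hsi_specimen <- function(x, ...) {
  cat(sprintf("<hsi_specimen> '%s'\n", x$id))
  print(x$cube)
  print(x$annotations)
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the tunable preprocessing and SVM parameters with the study's
#' settings as defaults.
#'
#' @param max_nm Band-selection cutoff (nm).
#' @param probe_nm Highlight/shadow probe wavelength (nm).
#' @param hi,lo Highlight/shadow reflectance thresholds (fractions).
#' @param floor Reflectance floor for absorbance.
#' @param space Feature representation, `"absorbance"` or `"reflectance"`.
#' @param C SVM regularization constant.
#' @param sigma2 RBF bandwidth or `"median"`.
#' @param c_scaling `"absolute"` or `"per_m"` (see [svm_train()]).
#' @param tol,max_iter Solver controls.
#' @param subsample Stratified cap on training spectra per class per fold:
#'   `"balance"` (default) caps both classes at the smaller class count, so
#'   the bias-free SVM's operating point is not shifted by the box-pixel
#'   class imbalance; an integer caps both classes at that count; `NULL`
#'   uses every box pixel.
#' @param subsample_seed Seed for the stratified draw (fixed by default so
#'   runs are reproducible).
#' @return A named list of class `gist_config`.
#' @export
loocv_config <- function(max_nm = 1600, probe_nm = 1300, hi = 0.70, lo = 0.10,
                         floor = 1e-4, space = "absorbance", C = 1,
                         sigma2 = "median", c_scaling = "absolute", tol = 1e-3,
                         max_iter = 1e7, subsample = "balance",
                         subsample_seed = 1L) {
  structure(
    list(
      max_nm = max_nm, probe_nm = probe_nm, hi = hi, lo = lo, floor = floor,
      space = space, C = C, sigma2 = sigma2, c_scaling = c_scaling, tol = tol,
      max_iter = max_iter, subsample = subsample, subsample_seed = subsample_seed
    ),
    class = "gist_config"
  )
}

# Per-specimen derived objects: validity mask, labels, exclusion mask,
# features, training rows.
prepare_specimen <- function(spec, config) {
  shape <- cube_spatial_dim(spec$cube)
  labels <- rasterize_labels(spec$annotations, shape)
  hs <- highlight_shadow_mask(spec$cube,
    probe_nm = config$probe_nm,
    hi = config$hi, lo = config$lo
  )
  tissue <- pixel_mask(labels != 0L, "specimen extent")
  valid <- mask_and(hs, tissue)
  excl <- exclusion_mask(spec$annotations, shape)
  features <- preprocess_cube(spec$cube, valid,
    max_nm = config$max_nm,
    floor = config$floor, space = config$space
  )
  training <- extract_training_set(features, spec$annotations, spec$id)
  list(
    id = spec$id, shape = shape, labels = labels, valid = valid,
    excl = excl, features = features, training = training
  )
}

subsample_training <- function(ts, cap, seed) {
  if (is.null(cap)) {
    return(ts)
  }
  if (identical(cap, "balance")) {
    cap <- min(table(ts$label))
    if (cap == max(table(ts$label))) {
      return(ts) # already balanced
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(ts$label), ts$label), function(idx) {
    if (length(idx) <= cap) idx else sort(sample(idx, cap))
  }), use.names = FALSE)
  keep <- sort(keep)
  hsi_training(
    ts$X[keep, , drop = FALSE], ts$label[keep], ts$specimen[keep],
    ts$pixel_index[keep, ], ts$wavelengths
  )
}

#' Leave-one-specimen-out cross-validation
#'
#' For each specimen, an SVM is trained on the training-box spectra of all
#' other specimens and used to predict every valid pixel of the held-out
#' specimen. Confusion counts are tallied over the evaluation domain (valid,
#' outside the boundary-exclusion corridor, non-background) and pooled
#' across specimens by summation.
#'
#' @param cohort List of [specimen_record()]s (length >= 2).
#' @param config A [loocv_config()].
#' @param verbose Print per-fold progress.
#' @return Object of class `gist_loocv`: per-specimen prediction maps
#'   (`predictions`, integer matrices coded 0 unpredicted / 1 normal /
#'   2 gist), per-specimen `counts`, `pooled` counts, per-fold model
#'   summaries, and the config. Use [tidy()] for the per-specimen table and
#'   [glance()] for pooled metrics.
#' @export
loocv_run <- function(cohort, config = loocv_config(), verbose = FALSE) {
  if (length(cohort) < 2L) {
    stop("leave-one-specimen-out needs at least 2 specimens", call. = FALSE)
  }
  prepared <- lapply(cohort, prepare_specimen, config = config)
  ids <- vapply(prepared, function(p) p$id, "")
  if (anyDuplicated(ids)) stop("duplicate specimen ids", call. = FALSE)

  predictions <- vector("list", length(prepared))
  counts <- vector("list", length(prepared))
  fold_info <- vector("list", length(prepared))

  for (k in seq_along(prepared)) {
    train_parts <- lapply(prepared[-k], function(p) p$training)
    ts <- bind_training(train_parts)
    if (length(unique(as.character(ts$label))) < 2L) {
      stop(sprintf(
        "fold holding out '%s' has a single training class", ids[k]
      ), call. = FALSE)
    }
    ts <- subsample_training(ts, config$subsample, config$subsample_seed)
    model <- svm_train(ts,
      C = config$C, sigma2 = config$sigma2,
      c_scaling = config$c_scaling, tol = config$tol,
      max_iter = config$max_iter
    )
    held <- prepared[[k]]
    pred_class <- predict(model, held$features$X)
    pred_map <- matrix(0L, held$shape[1], held$shape[2])
    pred_map[cbind(held$features$pixel_index$row, held$features$pixel_index$col)] <-
      ifelse(pred_class == "gist", 2L, 1L)
    predictions[[k]] <- pred_map
    counts[[k]] <- confusion(pred_map, held$labels, held$valid, held$excl)
    fold_info[[k]] <- tibble::tibble(
      held_out = ids[k],
      n_train = model$n_train,
      n_sv = length(model$alpha),
      sigma2 = model$sigma2,
      iterations = model$iterations,
      converged = model$converged
    )
    if (verbose) {
      message(sprintf(
        "fold %d/%d (held out %s): %d training spectra, %d SVs",
        k, length(prepared), ids[k], model$n_train, length(model$alpha)
      ))
    }
  }
  structure(
    list(
      ids = ids,
      predictions = stats::setNames(predictions, ids),
      counts = stats::setNames(counts, ids),
      pooled = pool_counts(counts),
      folds = dplyr::bind_rows(fold_info),
      prepared = prepared,
      config = config
    ),
    class = "gist_loocv"
  )
}

#' @export
print.gist_loocv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<gist_loocv> %d specimens, %d evaluated px\n", length(x$ids), g$total_px
  ))
  cat(sprintf(
    "  pooled specificity %.1f%%, sensitivity %.1f%%, accuracy %.1f%%\n",
    g$specificity, g$sensitivity, g$accuracy
  ))
  invisible(x)
}

#' Tidy a LOOCV result
#'
#' @param x A `gist_loocv`.
#' @param ... Unused.
#' @return The per-specimen results table (see [report_table()]).
#' @method tidy gist_loocv
#' @export
tidy.gist_loocv <- function(x, ...) {
  report_table(x)
}

#' Glance at a LOOCV result
#'
#' @param x A `gist_loocv`.
#' @param ... Unused.
#' @return One-row tibble of pooled counts and pooled (count-weighted)
#'   metrics in percent, unrounded.
#' @method glance gist_loocv
#' @export
glance.gist_loocv <- function(x, ...) {
  m <- metrics(x$pooled)
  tibble::tibble(
    n_specimens = length(x$ids),
    TP = x$pooled$TP, FN = x$pooled$FN, FP = x$pooled$FP, TN = x$pooled$TN,
    total_px = m$total_px,
    fpr = m$fpr, fnr = m$fnr,
    specificity = m$specificity, sensitivity = m$sensitivity,
    accuracy = m$accuracy
  )
}

#' Color-coded prediction overlay
#'
#' Renders predictions the way the study presents them: predicted GIST
#' pixels green, predicted normal pixels yellow, over a grayscale NIR base
#' image; masked and background pixels keep the base image. The `"merged"`
#' variant additionally leaves the boundary-exclusion corridor uncolored and
#' draws the pathologist's boundary polyline in blue.
#'
#' @param pred Prediction map (integer matrix: 0 none / 1 normal / 2 gist).
#' @param cube The specimen's calibrated [hsi_cube] (base image comes from
#'   the band nearest `base_nm`).
#' @param ann The specimen's [annotation_set].
#' @param variant `"full"` or `"merged"`.
#' @param excl Exclusion [pixel_mask]; computed from `ann` when omitted.
#' @param base_nm Wavelength of the grayscale base band.
#' @return An `rgb_image` array `[row, col, 3]` in `[0, 1]`.
#' @export
overlay <- function(pred, cube, ann, variant = c("full", "merged"),
                    excl = NULL, base_nm = 1300) {
  variant <- match.arg(variant)
  stopifnot_cube(cube)
  shape <- cube_spatial_dim(cube)
  if (!identical(dim(pred), shape)) {
    stop("prediction map shape does not match the cube", call. = FALSE)
  }
  base <- matrix(cube$values[, , nearest_band(cube, base_nm)], shape[1], shape[2])
  base[is.na(base)] <- 0
  lo <- min(base)
  hi <- max(base)
  gray <- if (hi > lo) (base - lo) / (hi - lo) else matrix(0, shape[1], shape[2])
  img <- array(rep(gray, 3), c(shape, 3L))

  colored <- pred != 0L
  if (variant == "merged") {
    if (is.null(excl)) excl <- exclusion_mask(ann, shape)
    colored <- colored & excl$values
  }
  gist_px <- colored & pred == 2L
  norm_px <- colored & pred == 1L
  img[, , 1][norm_px] <- 1
  img[, , 2][norm_px] <- 1
  img[, , 3][norm_px] <- 0
  img[, , 1][gist_px] <- 0
  img[, , 2][gist_px] <- 1
  img[, , 3][gist_px] <- 0

  if (variant == "merged") {
    on_line <- matrix(
      dist_to_polyline(grid_centers(shape), ann$boundary$vertices) <=
        max(ann$boundary$thickness_px / 2, 0.5),
      shape[1], shape[2],
      byrow = TRUE
    )
    img[, , 1][on_line] <- 0
    img[, , 2][on_line] <- 0
    img[, , 3][on_line] <- 1
  }
  structure(img, class = "rgb_image")
}

#' Write an RGB image as PNG
#'
#' @param img An `rgb_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("package 'png' is required to write PNG files", call. = FALSE)
  }
  png::writePNG(unclass(img), path)
  invisible(path)
}
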