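#' Specimen annotations: boundary line, training boxes, specimen extent
#'
#' The ground truth for one specimen: a closed boundary polyline drawn by a
#' pathologist separating the lesion (inside = GIST) from normal tissue
#' (outside), a set of axis-aligned training boxes each guaranteed to be one
#' tissue class, and the specimen extent separating tissue from the stage
#' background.
#'
#' Coordinates are pixel centers, 1-based `(row, col)`; boxes are inclusive
#' `[r0, r1] x [c0, c1]`.
#'
#' @param boundary List with `vertices` (n x 2 matrix of `(row, col)`, first
#'   vertex equal to the last) and `thickness_px` (nominal drawn line
#'   thickness `t`, pixels).
#' @param boxes Data frame with columns `label` (`"gist"`/`"normal"`), `r0`,
#'   `c0`, `r1`, `c1`.
#' @param extent List with `vertices`, a closed polygon enclosing the tissue.
#' @param validate Check box-label consistency against the boundary polygon
#'   (every gist box inside, every normal box outside).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(boundary, boxes, extent, validate = TRUE) {
  boundary$vertices <- as_vertex_matrix(boundary$vertices, "boundary")
  extent$vertices <- as_vertex_matrix(extent$vertices, "extent")
  boundary$thickness_px <- as.numeric(boundary$thickness_px %||% 0)
  if (boundary$thickness_px < 0) stop("boundary thickness must be >= 0", call. = FALSE)
  boxes <- tibble::as_tibble(boxes)
  req <- c("label", "r0", "c0", "r1", "c1")
  if (!all(req %in% names(boxes))) {
    stop("boxes need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(boxes) && !all(boxes$label %in% c("gist", "normal"))) {
    stop("box labels must be 'gist' or 'normal'", call. = FALSE)
  }
  if (nrow(boxes) && any(boxes$r1 < boxes$r0 | boxes$c1 < boxes$c0)) {
    stop("degenerate box: r1 < r0 or c1 < c0", call. = FALSE)
  }
  ann <- structure(
    list(boundary = boundary, boxes = boxes, extent = extent),
    class = "annotation_set"
  )
  if (validate) validate_boxes(ann)
  ann
}

as_vertex_matrix <- function(v, what) {
  if (is.list(v) && !is.data.frame(v)) v <- do.call(rbind, v)
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop(what, " vertices must be (row, col) pairs", call. = FALSE)
  if (nrow(v) < 4L) stop(what, " polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!isTRUE(all.equal(v[1, ], v[nrow(v), ]))) {
    stop(what, " polyline must be closed (first vertex = last)", call. = FALSE)
  }
  v
}

validate_boxes <- function(ann) {
  if (!nrow(ann$boxes)) {
    return(invisible(ann))
  }
  for (i in seq_len(nrow(ann$boxes))) {
    b <- ann$boxes[i, ]
    centers <- box_pixel_centers(b)
    inside <- point_in_polygon(centers, ann$boundary$vertices)
    in_extent <- point_in_polygon(centers, ann$extent$vertices)
    if (!all(in_extent)) {
      stop(sprintf("box %d (%s) extends outside the specimen extent", i, b$label),
        call. = FALSE
      )
    }
    if (b$label == "gist" && !all(inside)) {
      stop(sprintf("box %d labeled gist has pixels outside the boundary", i),
        call. = FALSE
      )
    }
    if (b$label == "normal" && any(inside)) {
      stop(sprintf("box %d labeled normal has pixels inside the boundary", i),
        call. = FALSE
      )
    }
  }
  invisible(ann)
}

box_pixel_centers <- function(b) {
  g <- expand.grid(
    row = seq(ceiling(b$r0), floor(b$r1)),
    col = seq(ceiling(b$c0), floor(b$c1))
  )
  cbind(g$row, g$col)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> boundary: %d vertices (t = %g px); %d boxes (%s); extent: %d vertices\n",
    nrow(x$boundary$vertices) - 1L, x$boundary$thickness_px, nrow(x$boxes),
    if (nrow(x$boxes)) paste(x$boxes$label, collapse = ", ") else "none",
    nrow(x$extent$vertices) - 1L
  ))
  invisible(x)
}

# Even-odd (crossing-number) point-in-polygon test on pixel centers.
# points: n x 2 (row, col); vertices: closed polygon. A point is inside if a
# ray cast in the +col direction crosses the polygon edges an odd number of
# times. Vectorized over points, looped over edges.
point_in_polygon <- function(points, vertices) {
  pr <- points[, 1]
  pc <- points[, 2]
  inside <- logical(length(pr))
  nv <- nrow(vertices) - 1L
  for (e in seq_len(nv)) {
    r1 <- vertices[e, 1]
    c1 <- vertices[e, 2]
    r2 <- vertices[e + 1L, 1]
    c2 <- vertices[e + 1L, 2]
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < (c2 - c1) * (pr - r1) / (r2 - r1) + c1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Load annotations from JSON
#'
#' Reads the interchange schema:
#' `{"boundary": {"vertices": [[r,c],...], "thickness_px": t},
#'   "boxes": [{"label": ..., "r0": ..., "c0": ..., "r1": ..., "c1": ...}],
#'   "extent": {"vertices": [...]}}`.
#'
#' @param path JSON file path.
#' @return A validated [annotation_set].
#' @export
load_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  boxes <- if (length(doc$boxes)) {
    tibble::as_tibble(doc$boxes)
  } else {
    tibble::tibble(
      label = character(), r0 = numeric(), c0 = numeric(),
      r1 = numeric(), c1 = numeric()
    )
  }
  annotation_set(
    boundary = list(
      vertices = doc$boundary$vertices,
      thickness_px = doc$boundary$thickness_px
    ),
    boxes = boxes,
    extent = list(vertices = doc$extent$vertices)
  )
}

#' Write annotations to JSON
#'
#' @param ann An [annotation_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  doc <- list(
    boundary = list(
      vertices = unname(ann$boundary$vertices),
      thickness_px = ann$boundary$thickness_px
    ),
    boxes = as.data.frame(ann$boxes),
    extent = list(vertices = unname(ann$extent$vertices))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize annotation ground truth to a label image
#'
#' Classifies every pixel center by the even-odd rule: inside the boundary
#' polygon is GIST, outside it but inside the specimen extent is normal
#' tissue, and outside the extent is background.
#'
#' @param ann An [annotation_set].
#' @param shape Integer `(rows, cols)` of the target grid.
#' @return A `label_image`: integer matrix coded 0 = background, 1 = normal,
#'   2 = gist, with a `labels` attribute naming the codes.
#' @export
rasterize_labels <- function(ann, shape) {
  if (polygon_area(ann$boundary$vertices) <= 0) {
    stop("degenerate boundary polygon (area 0)", call. = FALSE)
  }
  centers <- grid_centers(shape)
  in_extent <- point_in_polygon(centers, ann$extent$vertices)
  in_gist <- point_in_polygon(centers, ann$boundary$vertices)
  lab <- integer(nrow(centers))
  lab[in_extent] <- 1L
  lab[in_extent & in_gist] <- 2L
  out <- matrix(lab, shape[1], shape[2], byrow = TRUE)
  structure(out,
    class = "label_image",
    labels = c(background = 0L, normal = 1L, gist = 2L)
  )
}

grid_centers <- function(shape) {
  # row-major enumeration of pixel centers
  cbind(
    rep(seq_len(shape[1]), each = shape[2]),
    rep(seq_len(shape[2]), times = shape[1])
  )
}

polygon_area <- function(vertices) {
  n <- nrow(vertices) - 1L
  r <- vertices[seq_len(n), 1]
  c <- vertices[seq_len(n), 2]
  r2 <- vertices[seq_len(n) + 1L, 1]
  c2 <- vertices[seq_len(n) + 1L, 2]
  abs(sum(c * r2 - c2 * r)) / 2
}

#' Boundary-exclusion mask
#'
#' The boundary line is drawn freehand and therefore carries positional
#' error; for accuracy accounting its thickness is doubled on both the
#' inside and the outside, and pixels falling in that corridor are excluded.
#' A pixel is excluded iff its center lies within Euclidean distance `2 t`
#' of the boundary polyline, where `t` is the drawn line's nominal
#' thickness in pixels.
#'
#' @param ann An [annotation_set].
#' @param shape Integer `(rows, cols)` grid shape.
#' @return A [pixel_mask]; `TRUE` = retained (outside the corridor).
#' @export
exclusion_mask <- function(ann, shape) {
  t_px <- ann$boundary$thickness_px
  d <- dist_to_polyline(grid_centers(shape), ann$boundary$vertices)
  keep <- matrix(d > 2 * t_px, shape[1], shape[2], byrow = TRUE)
  pixel_mask(keep, sprintf(
    "boundary exclusion: drop dist <= 2t = %g px", 2 * t_px
  ))
}

# Minimum Euclidean distance from each point to a closed polyline,
# vectorized over points, looped over segments.
dist_to_polyline <- function(points, vertices) {
  pr <- points[, 1]
  pc <- points[, 2]
  dmin <- rep(Inf, length(pr))
  for (e in seq_len(nrow(vertices) - 1L)) {
    ar <- vertices[e, 1]
    ac <- vertices[e, 2]
    br <- vertices[e + 1L, 1]
    bc <- vertices[e + 1L, 2]
    vr <- br - ar
    vc <- bc - ac
    len2 <- vr * vr + vc * vc
    tt <- if (len2 > 0) pmin(1, pmax(0, ((pr - ar) * vr + (pc - ac) * vc) / len2)) else 0
    dr <- pr - (ar + tt * vr)
    dc <- pc - (ac + tt * vc)
    dmin <- pmin(dmin, sqrt(dr * dr + dc * dc))
  }
  dmin
}

#' Labeled training set
#'
#' Preprocessed spectra with class labels, pixel coordinates and specimen
#' provenance (needed for leave-one-specimen-out folds).
#'
#' @param X Numeric feature matrix, one spectrum per row.
#' @param label Factor or character, `"gist"`/`"normal"` per row.
#' @param specimen Specimen id per row.
#' @param pixel_index Tibble of `row`, `col` per row.
#' @param wavelengths Band centers for the feature columns.
#' @return Object of class `hsi_training`.
#' @export
hsi_training <- function(X, label, specimen, pixel_index, wavelengths) {
  label <- factor(as.character(label), levels = c("gist", "normal"))
  stopifnot(
    nrow(X) == length(label),
    nrow(X) == length(specimen),
    nrow(X) == nrow(pixel_index)
  )
  structure(
    list(
      X = X, label = label, specimen = as.character(specimen),
      pixel_index = tibble::as_tibble(pixel_index),
      wavelengths = as.numeric(wavelengths)
    ),
    class = "hsi_training"
  )
}

#' @export
print.hsi_training <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf(
    "<hsi_training> %d spectra x %d bands (gist: %d, normal: %d) from %d specimen(s)\n",
    nrow(x$X), ncol(x$X), tab[["gist"]], tab[["normal"]],
    length(unique(x$specimen))
  ))
  invisible(x)
}

#' @rdname hsi_training
#' @param x An `hsi_training` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with specimen, pixel coordinates and label per
#'   training spectrum.
#' @method tidy hsi_training
#' @export
tidy.hsi_training <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(specimen = x$specimen),
    x$pixel_index,
    tibble::tibble(label = x$label)
  )
}

#' Extract box-labeled training spectra from a feature matrix
#'
#' Selects the feature rows whose pixels fall inside a training box (and so
#' survived the validity masks) and labels them with the box's class.
#'
#' @param features An [hsi_features] from [preprocess_cube()].
#' @param ann An [annotation_set].
#' @param specimen_id Id recorded per row (for LOOCV folds).
#' @return An [hsi_training]. Errors if any box yields zero valid pixels.
#' @export
extract_training_set <- function(features, ann, specimen_id = "specimen") {
  if (!nrow(ann$boxes)) stop("annotation set has no training boxes", call. = FALSE)
  rows <- features$pixel_index$row
  cols <- features$pixel_index$col
  picked <- integer(0)
  labels <- character(0)
  for (i in seq_len(nrow(ann$boxes))) {
    b <- ann$boxes[i, ]
    in_box <- which(rows >= b$r0 & rows <= b$r1 & cols >= b$c0 & cols <= b$c1)
    if (!length(in_box)) {
      stop(sprintf(
        "box %d (%s, rows %g-%g cols %g-%g) yields zero valid pixels",
        i, b$label, b$r0, b$r1, b$c0, b$c1
      ), call. = FALSE)
    }
    picked <- c(picked, in_box)
    labels <- c(labels, rep(b$label, length(in_box)))
  }
  hsi_training(
    X = features$X[picked, , drop = FALSE],
    label = labels,
    specimen = rep(specimen_id, length(picked)),
    pixel_index = features$pixel_index[picked, ],
    wavelengths = features$wavelengths
  )
}

#' Concatenate training sets
#'
#' @param ... `hsi_training` objects with identical wavelength axes.
#' @return A single [hsi_training].
#' @export
bind_training <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "hsi_training")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L)
  wl <- parts[[1]]$wavelengths
  for (p in parts) {
    if (!isTRUE(all.equal(p$wavelengths, wl))) {
      stop("training sets have mismatched wavelength axes", call. = FALSE)
    }
  }
  hsi_training(
    X = do.call(rbind, lapply(parts, function(p) p$X)),
    label = unlist(lapply(parts, function(p) as.character(p$label))),
    specimen = unlist(lapply(parts, function(p) p$specimen)),
    pixel_index = dplyr::bind_rows(lapply(parts, function(p) p$pixel_index)),
    wavelengths = wl
  )
}
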