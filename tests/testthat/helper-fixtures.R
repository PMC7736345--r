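# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# small calibrated reflectance cube on the instrument grid
toy_cube <- function(nr = 4, nc = 4, nb = 96, fill = NULL, seed = 42) {
  set.seed(seed)
  vals <- if (is.null(fill)) {
    array(runif(nr * nc * nb, 0.2, 0.6), c(nr, nc, nb))
  } else {
    array(fill, c(nr, nc, nb))
  }
  hsi_cube(vals, default_wavelengths(nb), meta = list(calibrated = TRUE))
}

# square annotation: boundary square [b0, b1], extent square [e0, e1]
# (coordinates are pixel centers; the .5 offsets put edges between centers)
square_annotation <- function(b0, b1, e0, e1, thickness = 1, boxes = NULL) {
  sq <- function(lo, hi) {
    rbind(
      c(lo, lo), c(lo, hi), c(hi, hi), c(hi, lo), c(lo, lo)
    )
  }
  if (is.null(boxes)) {
    boxes <- tibble::tibble(
      label = character(), r0 = numeric(), c0 = numeric(),
      r1 = numeric(), c1 = numeric()
    )
  }
  annotation_set(
    boundary = list(vertices = sq(b0, b1), thickness_px = thickness),
    boxes = boxes,
    extent = list(vertices = sq(e0, e1)),
    validate = nrow(boxes) > 0
  )
}

# two well-separated Gaussian clusters, one per class
separable_set <- function(n_per_class = 10, d = 5, p = 4, seed = 1, sd = 0.2) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p),
    matrix(rnorm(n_per_class * p, d / sqrt(p), sd), n_per_class, p)
  )
  label <- rep(c("gist", "normal"), each = n_per_class)
  list(X = X, label = label)
}

# small synthetic cohort for pipeline tests (fast: 40x40 grid)
small_cohort <- function(n = 4, seed = 7, n_gist_only = 1, separation = 1.5,
                         noise_sd = 0.02, ...) {
  cfg <- cohort_config(
    specimen = specimen_config(shape = c(48, 48), box_size = 6, ...),
    separation = separation,
    n_gist_only = n_gist_only
  )
  cfg$specimen$noise_sd <- noise_sd
  make_cohort(n, cfg, seed = seed)
}
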