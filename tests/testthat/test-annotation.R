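test_that("annotation JSON round-trips through the interchange schema", {
  boxes <- tibble::tibble(
    label = c("gist", "normal"), r0 = c(3, 1), c0 = c(3, 6),
    r1 = c(4, 1), c1 = c(4, 7)
  )
  ann <- square_annotation(2.5, 4.5, 0.5, 7.5, thickness = 2, boxes = boxes)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- load_annotations(path)
  expect_equal(back$boundary$vertices, ann$boundary$vertices)
  expect_equal(back$boundary$thickness_px, 2)
  expect_equal(as.data.frame(back$boxes), as.data.frame(ann$boxes))
  expect_equal(back$extent$vertices, ann$extent$vertices)
})

test_that("invalid annotations are rejected with informative errors", {
  open_poly <- rbind(c(1, 1), c(1, 5), c(5, 5), c(5, 1)) # not closed
  expect_error(
    annotation_set(
      boundary = list(vertices = open_poly, thickness_px = 1),
      boxes = tibble::tibble(
        label = character(), r0 = numeric(), c0 = numeric(),
        r1 = numeric(), c1 = numeric()
      ),
      extent = list(vertices = rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0), c(0, 0)))
    ),
    "closed"
  )
  # normal-labeled box inside the boundary
  expect_error(
    square_annotation(2.5, 6.5, 0.5, 9.5, boxes = tibble::tibble(
      label = "normal", r0 = 4, c0 = 4, r1 = 5, c1 = 5
    )),
    "box 1 labeled normal"
  )
  # gist-labeled box outside the boundary
  expect_error(
    square_annotation(2.5, 6.5, 0.5, 9.5, boxes = tibble::tibble(
      label = "gist", r0 = 8, c0 = 8, r1 = 9, c1 = 9
    )),
    "box 1 labeled gist"
  )
})

test_that("rasterization classifies pixel centers by the even-odd rule", {
  # 3x3 boundary square inside a 7x7 extent: 9 gist, 40 normal
  ann <- square_annotation(1.5, 4.5, 0.5, 7.5)
  lab <- rasterize_labels(ann, c(7, 7))
  expect_equal(sum(lab == 2L), 9L)
  expect_equal(sum(lab == 1L), 40L)
  expect_equal(sum(lab == 0L), 0L)
  expect_true(all(lab[2:4, 2:4] == 2L))

  # independent scalar oracle agrees on irregular polygons
  set.seed(21)
  for (i in 1:5) {
    theta <- seq(0, 2 * pi, length.out = 13)[-13]
    r <- 8 + runif(12, -3, 3)
    v <- cbind(10 + r * sin(theta), 10 + r * cos(theta))
    v <- rbind(v, v[1, ])
    ann_i <- annotation_set(
      boundary = list(vertices = v, thickness_px = 1),
      boxes = tibble::tibble(
        label = character(), r0 = numeric(), c0 = numeric(),
        r1 = numeric(), c1 = numeric()
      ),
      extent = list(vertices = rbind(
        c(0.5, 0.5), c(0.5, 20.5), c(20.5, 20.5), c(20.5, 0.5), c(0.5, 0.5)
      ))
    )
    lab_i <- rasterize_labels(ann_i, c(20, 20))
    oracle <- oracle_rasterize_counts(ann_i, c(20, 20))
    expect_equal(sum(lab_i == 2L), unname(oracle["gist"]))
    expect_equal(sum(lab_i == 1L), unname(oracle["normal"]))
    expect_equal(sum(lab_i == 0L), unname(oracle["background"]))
  }
})

test_that("rasterization partitions the extent and degenerate boundaries error", {
  ann <- square_annotation(1.5, 4.5, 0.5, 7.5)
  lab <- rasterize_labels(ann, c(9, 9))
  in_ext <- sum(lab != 0L)
  expect_equal(sum(lab == 2L) + sum(lab == 1L), in_ext)

  # boundary equal to the extent: zero normal pixels
  ann_eq <- square_annotation(0.5, 7.5, 0.5, 7.5)
  lab_eq <- rasterize_labels(ann_eq, c(8, 8))
  expect_equal(sum(lab_eq == 1L), 0L)
  expect_gt(sum(lab_eq == 2L), 0L)

  degenerate <- annotation_set(
    boundary = list(vertices = rbind(c(2, 2), c(2, 2), c(2, 2), c(2, 2)), thickness_px = 1),
    boxes = tibble::tibble(
      label = character(), r0 = numeric(), c0 = numeric(),
      r1 = numeric(), c1 = numeric()
    ),
    extent = list(vertices = rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0), c(0, 0)))
  )
  expect_error(rasterize_labels(degenerate, c(9, 9)), "degenerate")
})

test_that("exclusion corridor is the 2t-neighborhood of the boundary polyline", {
  # straight segment of thickness 1 along row 5 of an 11-row grid:
  # rows 3-7 excluded (distance <= 2)
  v <- rbind(c(5, -10), c(5, 30), c(5.0001, 30), c(5.0001, -10), c(5, -10))
  ann <- annotation_set(
    boundary = list(vertices = v, thickness_px = 1),
    boxes = tibble::tibble(
      label = character(), r0 = numeric(), c0 = numeric(),
      r1 = numeric(), c1 = numeric()
    ),
    extent = list(vertices = rbind(
      c(0.5, 0.5), c(0.5, 11.5), c(11.5, 11.5), c(11.5, 0.5), c(0.5, 0.5)
    ))
  )
  excl <- exclusion_mask(ann, c(11, 11))
  excluded_rows <- which(apply(!excl$values, 1, any))
  expect_equal(excluded_rows, 3:7)
  expect_true(all(!excl$values[3:7, ]))

  # t = 0: only pixels on the line excluded
  ann0 <- ann
  ann0$boundary$thickness_px <- 0
  excl0 <- exclusion_mask(ann0, c(11, 11))
  expect_equal(which(apply(!excl0$values, 1, any)), 5L)
})

test_that("exclusion area grows monotonically with line thickness", {
  ann <- square_annotation(5.5, 14.5, 0.5, 20.5)
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(t) {
    a <- ann
    a$boundary$thickness_px <- t
    sum(!exclusion_mask(a, c(20, 20))$values)
  }, 1)
  expect_true(all(diff(counts) >= 0))
  # brute-force distance transform agrees
  a2 <- ann
  a2$boundary$thickness_px <- 1.5
  expect_equal(
    sum(!exclusion_mask(a2, c(20, 20))$values),
    oracle_excluded_count(ann, c(20, 20), 1.5)
  )
})

test_that("training-set extraction labels box pixels and conserves counts", {
  cube <- toy_cube(8, 8, 96, seed = 13)
  mask <- pixel_mask(matrix(TRUE, 8, 8))
  fm <- preprocess_cube(cube, mask)
  boxes <- tibble::tibble(
    label = c("gist", "normal"), r0 = c(4, 1), c0 = c(4, 7),
    r1 = c(5, 2), c1 = c(5, 8)
  )
  ann <- square_annotation(2.5, 6.5, 0.5, 8.5, boxes = boxes)
  ts <- extract_training_set(fm, ann, "s1")
  expect_s3_class(ts, "hsi_training")
  expect_equal(sum(ts$label == "gist"), 4L)
  expect_equal(sum(ts$label == "normal"), 4L)
  expect_equal(unique(ts$specimen), "s1")
  # tidy() exposes the per-row provenance
  td <- tidy(ts)
  expect_named(td, c("specimen", "row", "col", "label"))

  # a box wiped out by masking errors, naming the box
  mask2 <- matrix(TRUE, 8, 8)
  mask2[4:5, 4:5] <- FALSE
  fm2 <- preprocess_cube(cube, pixel_mask(mask2))
  expect_error(extract_training_set(fm2, ann, "s1"), "box 1 .*zero valid")
})
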