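# Independent oracles. These deliberately use different algorithms from the
# package implementation so that agreement is evidence of correctness.

# Projected-gradient ascent on the bias-free SVM dual
#   max  sum(alpha) - 1/2 alpha' Q alpha,  0 <= alpha <= Cb,
# with Q = (s s') * K. Fixed step 1/L (L = largest eigenvalue of Q),
# provably convergent on this box-constrained concave QP; run to high
# precision. Independent of the package's coordinate-decomposition solver.
oracle_svm_dual <- function(K, s, Cb, iters = 200000) {
  Q <- K * outer(s, s)
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  step <- 1 / L
  alpha <- rep(Cb / 2, length(s))
  for (i in seq_len(iters)) {
    g <- 1 - as.numeric(Q %*% alpha)
    alpha_new <- pmin(Cb, pmax(0, alpha + step * g))
    if (max(abs(alpha_new - alpha)) < 1e-14) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  obj <- sum(alpha) - 0.5 * sum(alpha * as.numeric(Q %*% alpha))
  list(alpha = alpha, objective = obj)
}

oracle_svm_predict <- function(oracle, K_test_train, s, classes = c("gist", "normal")) {
  f <- as.numeric(K_test_train %*% (oracle$alpha * s))
  factor(ifelse(f >= 0, classes[1], classes[2]), levels = classes)
}

# Scalar (non-vectorized) even-odd point-in-polygon test, written
# independently of the package's vectorized version.
oracle_point_in_polygon <- function(r, c, vertices) {
  inside <- FALSE
  n <- nrow(vertices) - 1L
  for (e in seq_len(n)) {
    r1 <- vertices[e, 1]; c1 <- vertices[e, 2]
    r2 <- vertices[e + 1L, 1]; c2 <- vertices[e + 1L, 2]
    if ((r1 > r) != (r2 > r)) {
      c_at <- c1 + (r - r1) / (r2 - r1) * (c2 - c1)
      if (c < c_at) inside <- !inside
    }
  }
  inside
}

oracle_rasterize_counts <- function(ann, shape) {
  gist <- 0L; normal <- 0L; background <- 0L
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      in_ext <- oracle_point_in_polygon(r, c, ann$extent$vertices)
      if (!in_ext) {
        background <- background + 1L
      } else if (oracle_point_in_polygon(r, c, ann$boundary$vertices)) {
        gist <- gist + 1L
      } else {
        normal <- normal + 1L
      }
    }
  }
  c(gist = gist, normal = normal, background = background)
}

# brute-force distance-transform exclusion count
oracle_excluded_count <- function(ann, shape, t_px) {
  v <- ann$boundary$vertices
  count <- 0L
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      dmin <- Inf
      for (e in seq_len(nrow(v) - 1L)) {
        a <- v[e, ]; b <- v[e + 1L, ]
        ab <- b - a
        len2 <- sum(ab^2)
        tt <- if (len2 > 0) min(1, max(0, sum((c(r, c) - a) * ab) / len2)) else 0
        dmin <- min(dmin, sqrt(sum((c(r, c) - (a + tt * ab))^2)))
      }
      if (dmin <= 2 * t_px) count <- count + 1L
    }
  }
  count
}
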