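test_that("median-heuristic bandwidth matches hand-computed pair medians", {
  expect_equal(median_sigma2(rbind(c(0, 0), c(3, 4))), 25)
  # distances^2 {1, 1, 2} -> median 1
  expect_equal(median_sigma2(rbind(c(0, 0), c(1, 0), c(0, 1))), 1)
  # even pair count: mean of central values; 4 points on a line 0,1,2,3:
  # d2 = {1,4,9,1,4,1} -> sorted {1,1,1,4,4,9} -> median 2.5
  expect_equal(median_sigma2(cbind(c(0, 1, 2, 3))), 2.5)
  expect_error(median_sigma2(rbind(c(1, 1), c(1, 1))), "zero")
})

test_that("median bandwidth is permutation/translation invariant and scales as c^2", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  s2 <- median_sigma2(X)
  expect_equal(median_sigma2(X[sample(10), ]), s2)
  expect_equal(median_sigma2(sweep(X, 2, c(5, -2, 0.3, 7), "+")), s2)
  expect_equal(median_sigma2(3 * X), 9 * s2)
})

test_that("RBF kernel values and PSD property hold", {
  x <- rnorm(5)
  expect_equal(rbf_kernel(x, x, sigma2 = 2)[1, 1], 1)
  # squared distance equal to sigma2 -> exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma2 = 25)[1, 1], exp(-1))
  expect_error(rbf_kernel(x, x, sigma2 = 0), "positive")

  set.seed(32)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    K <- rbf_kernel(X, sigma2 = median_sigma2(X))
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }
})

test_that("two opposite-class points are separated with zero decision at the midpoint", {
  X <- rbind(c(0, 0), c(2, 0))
  fit <- svm_train(X, label = c("gist", "normal"), C = 1, sigma2 = 4, tol = 1e-8)
  expect_equal(as.character(predict(fit, X)), c("gist", "normal"))
  mid <- rbind(c(1, 0))
  sc <- decision_values(fit, mid)
  expect_equal(unname(sc[1, "gist"]), unname(sc[1, "normal"]), tolerance = 1e-9)
  # exact tie resolves to the first class code
  expect_equal(as.character(predict(fit, mid)), "gist")

  # analytic dual: both alphas clipped at the box bound 2C/m = 1
  expect_equal(sort(fit$alpha), c(1, 1), tolerance = 1e-6)
})

test_that("under C/m scaling, duplicating every training point leaves the decision unchanged", {
  ts <- separable_set(n_per_class = 6, d = 3, seed = 33)
  fit1 <- svm_train(ts$X, label = ts$label, sigma2 = 2, tol = 1e-8, c_scaling = "per_m")
  fit2 <- svm_train(rbind(ts$X, ts$X),
    label = c(ts$label, ts$label),
    sigma2 = 2, tol = 1e-8, c_scaling = "per_m"
  )
  probe <- matrix(rnorm(40), 10, 4)
  expect_equal(decision_values(fit2, probe), decision_values(fit1, probe),
    tolerance = 1e-5
  )
})

test_that("a separable 20-point set is fit with zero training errors and vanishing slack", {
  ts <- separable_set(n_per_class = 10, d = 6, seed = 34)
  fit <- svm_train(ts$X, label = ts$label, C = 50, tol = 1e-8)
  expect_equal(as.character(predict(fit, ts$X)), ts$label)
  expect_true(all(fit$slack <= 1e-6))
})

test_that("slack decreases toward zero as C grows on separable data", {
  ts <- separable_set(n_per_class = 8, d = 4, seed = 35)
  slacks <- vapply(c(0.5, 2, 8, 32, 128), function(C) {
    sum(svm_train(ts$X, label = ts$label, C = C, sigma2 = 3, tol = 1e-8)$slack)
  }, 1)
  expect_true(all(diff(slacks) <= 1e-8))
  expect_lt(slacks[length(slacks)], 1e-6)
})

test_that("the decomposition solver matches the projected-gradient dual oracle", {
  set.seed(36)
  for (i in 1:10) {
    m <- sample(4:12, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(m * p), m, p)
    y <- c("gist", "normal", sample(c("gist", "normal"), m - 2, replace = TRUE))
    s2 <- median_sigma2(X)
    s <- ifelse(y == "gist", 1, -1)
    K <- rbf_kernel(X, sigma2 = s2)
    for (scaling in c("absolute", "per_m")) {
      fit <- svm_train(X, label = y, C = 1, sigma2 = s2, tol = 1e-9, c_scaling = scaling)
      oracle <- oracle_svm_dual(K, s, Cb = fit$box_bound)
      expect_equal(fit$objective_dual, oracle$objective, tolerance = 1e-7)
      expect_equal(
        as.character(predict(fit, X)),
        as.character(oracle_svm_predict(oracle, K, s))
      )
    }
  }
})

test_that("dual feasibility and complementary slackness hold at the solution", {
  ts <- separable_set(n_per_class = 7, d = 2, seed = 37, sd = 0.8)
  fit <- svm_train(ts$X, label = ts$label, C = 1, tol = 1e-6)
  Cb <- fit$box_bound
  expect_true(all(fit$alpha > 0 & fit$alpha <= Cb + 1e-12))
  # full dual vector: zero off the support set
  alpha_full <- numeric(fit$n_train)
  alpha_full[fit$sv_index] <- fit$alpha
  # strict slack requires alpha at the box bound
  slacked <- which(fit$slack > 1e-3)
  expect_true(all(abs(alpha_full[slacked] - Cb) <= 1e-9))
  # interior (free) dual variables sit on the margin: s_i f(x_i) = 1
  s <- ifelse(ts$label == "gist", 1, -1)
  free <- which(alpha_full > 1e-9 & alpha_full < Cb - 1e-9)
  if (length(free)) {
    expect_equal(s[free] * fit$f_train[free], rep(1, length(free)),
      tolerance = 1e-3
    )
  }
})

test_that("decision values are self-consistent, antisymmetric and smooth", {
  ts <- separable_set(n_per_class = 8, d = 3, seed = 38)
  fit <- svm_train(ts$X, label = ts$label, tol = 1e-8)
  sc <- decision_values(fit, ts$X)
  # class scores are antisymmetric in the binary reduction
  expect_equal(sc[, 1], -sc[, 2], tolerance = 1e-12)
  # scores at training points reproduce training-time decision values
  expect_equal(2 * sc[, "gist"], fit$f_train, tolerance = 1e-9)
  # numeric perturbation: RBF smoothness bounds the score change
  probe <- ts$X[1, , drop = FALSE]
  eps <- 1e-5
  d0 <- decision_values(fit, probe)[1, 1]
  d1 <- decision_values(fit, probe + eps)[1, 1]
  lipschitz <- sum(abs(fit$coef)) * sqrt(2 / (fit$sigma2 * exp(1))) / 2
  expect_lt(abs(d1 - d0), lipschitz * eps * sqrt(ncol(probe)) + 1e-12)
})

test_that("prediction is equivariant under row permutation", {
  ts <- separable_set(n_per_class = 6, d = 2, seed = 39, sd = 1)
  fit <- svm_train(ts$X, label = ts$label)
  probe <- matrix(rnorm(48), 12, 4)
  perm <- sample(12)
  expect_equal(predict(fit, probe)[perm], predict(fit, probe[perm, ]))
})

test_that("training errors on degenerate inputs are informative", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(svm_train(X, label = rep("gist", 5)), "single class")
  expect_error(svm_train(X, label = rep(c("gist", "normal"), c(3, 2)), sigma2 = -1), "positive")
})

test_that("predictions agree with an independent reference SVM on separated clusters", {
  skip_if_not_installed("e1071")
  ts <- separable_set(n_per_class = 15, d = 8, seed = 40, sd = 0.5)
  s2 <- median_sigma2(ts$X)
  fit <- svm_train(ts$X, label = ts$label, C = 30, sigma2 = s2, tol = 1e-8)
  ref <- e1071::svm(ts$X, factor(ts$label),
    kernel = "radial", gamma = 1 / s2,
    cost = 10, scale = FALSE
  )
  probe <- rbind(
    ts$X + matrix(rnorm(nrow(ts$X) * 4, 0, 0.3), ncol = 4)
  )
  expect_equal(
    as.character(predict(fit, probe)),
    as.character(predict(ref, probe))
  )
})
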