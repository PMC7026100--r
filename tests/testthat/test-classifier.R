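test_that("standardization uses training-fold statistics only", {
  x <- matrix(c(0, 2, 4, 10, 1, 3, 5, 7), ncol = 2)
  std <- impute_and_standardize(x, training_rows = 1:3)
  expect_equal(colMeans(std$x[1:3, ]), c(0, 0), tolerance = 1e-12)

  # already standardized input is (close to) untouched
  set.seed(1)
  z <- scale(matrix(rnorm(60), 20, 3))
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  std2 <- impute_and_standardize(z)
  expect_equal(unclass(std2$x), unclass(z), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a missing value is replaced by the training mean
  xm <- matrix(c(1, 2, 3, NA), ncol = 1)
  out <- impute_and_standardize(xm, training_rows = 1:3)
  expect_equal(out$x[4, 1], 0) # imputed at the center

  # no leakage: the transform ignores the held-out row entirely
  x2 <- x; x2[4, ] <- c(1e6, -1e6)
  t1 <- impute_and_standardize(x, 1:3)$transform
  t2 <- impute_and_standardize(x2, 1:3)$transform
  expect_identical(t1, t2)

  zv <- matrix(c(5, 5, 5, 1, 2, 3), ncol = 2)
  expect_message(impute_and_standardize(zv), "zero-variance")
})

test_that("PCA keeps the smallest sufficient component set", {
  set.seed(2)
  u <- rnorm(100)
  line <- cbind(u, 2 * u) + matrix(rnorm(200, sd = 1e-6), ncol = 2)
  p <- fit_pca(scale(line), 0.95)
  expect_equal(p$k, 1)
  expect_gt(p$explained[1], 0.999)

  iso <- matrix(rnorm(2000 * 5), ncol = 5)
  expect_equal(fit_pca(impute_and_standardize(iso)$x, 0.95)$k, 5)

  # reconstruction error equals the sum of the discarded eigenvalues
  set.seed(3)
  x <- impute_and_standardize(matrix(rnorm(400), 80, 5) %*%
                                diag(c(3, 2, 1, 0.5, 0.2)))$x
  p2 <- fit_pca(x, 0.8)
  recon <- project_pca(p2, x) %*% t(p2$rotation)
  err <- sum((x - recon)^2) / (nrow(x) - 1)
  expect_equal(err, sum(p2$eigenvalues[-seq_len(p2$k)]), tolerance = 1e-9)
  expect_error(fit_pca(x[1, , drop = FALSE]), "2 rows")
})

test_that("the stump solves separable 1D data and degenerate labels", {
  m <- fit_stump(matrix(1:4, ncol = 1), c(0, 0, 1, 1))
  expect_equal(m$threshold, 2.5)
  expect_equal(m$training_error, 0L)
  expect_equal(as.character(predict_stump(m, matrix(c(2, 3), ncol = 1))),
               c("0", "1"))

  const <- fit_stump(matrix(rnorm(8), ncol = 2), rep("a", 4))
  expect_equal(const$polarity, "constant")
  expect_equal(const$training_error, 0L)
  expect_equal(as.character(predict_stump(const, matrix(0, 1, 2))), "a")
})

test_that("stump training error matches exhaustive enumeration", {
  set.seed(4)
  for (rep in 1:100) {
    x <- matrix(rnorm(30), 10, 3)
    y <- sample(0:1, 10, replace = TRUE)
    m <- fit_stump(x, y)
    expect_equal(as.integer(m$training_error), oracle_stump_error(x, y))
  }
})

test_that("leave-one-out separates well-separated classes and not null ones", {
  set.seed(5)
  n <- 40
  x <- rbind(matrix(rnorm(n / 2 * 4), ncol = 4),
             matrix(rnorm(n / 2 * 4, mean = 6), ncol = 4))
  y <- rep(c("a", "b"), each = n / 2)
  res <- suppressMessages(loo_evaluate(x, y))
  expect_gte(res$accuracy, 0.95)
  expect_equal(sum(res$confusion), n)

  yperm <- sample(y)
  res0 <- suppressMessages(
    loo_evaluate(matrix(rnorm(n * 4), ncol = 4), yperm))
  band <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(res0$accuracy, band[1])
  expect_lte(res0$accuracy, band[2])
})

test_that("LOO predictions are invariant to row order", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30), ncol = 3),
             matrix(rnorm(30, mean = 3), ncol = 3))
  y <- rep(c("a", "b"), each = 10)
  ids <- sprintf("d%02d", 1:20)
  r1 <- suppressMessages(loo_evaluate(x, y, dyad_id = ids))
  perm <- sample(20)
  r2 <- suppressMessages(loo_evaluate(x[perm, ], y[perm],
                                      dyad_id = ids[perm]))
  expect_equal(r2$predicted[match(ids, r2$dyad_id)], r1$predicted)
})

test_that("point-biserial correlations match the closed form and ranking", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(2, 1, 3, 6, 5, 7)
  got <- feature_class_correlations(matrix(x, ncol = 1,
                                           dimnames = list(NULL, "f")),
                                    y)
  # textbook point-biserial on the 6-row table
  n1 <- 3; n0 <- 3; n <- 6
  r_oracle <- (mean(x[y == 1]) - mean(x[y == 0])) /
    sqrt(sum((x - mean(x))^2) / n) * sqrt(n1 * n0 / n^2)
  t_stat <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_stat), n - 2)
  expect_equal(got$r, r_oracle, tolerance = 1e-9)
  expect_equal(got$p, p_oracle, tolerance = 1e-9)

  # feature equal to the label: perfect correlation
  perf <- feature_class_correlations(
    matrix(as.numeric(y), ncol = 1, dimnames = list(NULL, "lab")), y)
  expect_equal(perf$r, 1)
  expect_lt(perf$p, 1e-12)

  set.seed(7)
  nul <- feature_class_correlations(
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "z")),
    sample(0:1, 1000, replace = TRUE))
  expect_lt(abs(nul$r), 0.1)

  # constant features are excluded, ranking is by |r|
  xx <- cbind(weak = c(1, 2, 1, 3, 2, 4), strong = c(0, 1, 0, 5, 6, 7),
              flat = rep(2, 6))
  rk <- suppressMessages(feature_class_correlations(xx, y))
  expect_equal(rk$feature[1], "strong")
  expect_false("flat" %in% rk$feature)
})

test_that("accuracy arithmetic reproduces the reported percentages", {
  expect_equal(accuracy_from_counts(51, 12), 76.47)
  expect_equal(accuracy_from_counts(32, 6), 81.25)
  expect_equal(accuracy_from_counts(17, 0), 100)
  expect_error(accuracy_from_counts(0, 0), "positive")
  expect_error(accuracy_from_counts(10, 11), "n_errors")
})
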