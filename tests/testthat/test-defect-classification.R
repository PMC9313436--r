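make_toy_tiles <- function(n = 40, side = 12, seed = 7) {
  # tiles varying along exactly two generative axes (bar position and bar
  # width) plus sparse salt noise
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(0L, side, side)
    pos <- sample(3:(side - 3), 1)
    w <- sample(1:3, 1)
    m[, pos:(pos + w - 1)] <- 1L
    noise <- sample(length(m), 2)
    m[noise] <- 1L - m[noise]
    binary_mask(m)
  })
}

test_that("Gram-trick PCA matches the direct eigendecomposition", {
  tiles <- make_toy_tiles()
  proj <- fit_pixel_pca(tiles, n_components = 5)
  X <- do.call(rbind, lapply(tiles, function(t) as.numeric(unclass(t))))
  # direct covariance eigendecomposition oracle
  S <- cov(X)
  eo <- eigen(S, symmetric = TRUE)
  expect_equal(proj$sdev[1:5]^2, eo$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    # components agree up to sign
    expect_equal(abs(sum(proj$rotation[, k] * eo$vectors[, k])), 1,
                 tolerance = 1e-6)
  }
  # orthonormality
  expect_equal(crossprod(proj$rotation), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("two generative axes dominate the explained variance", {
  tiles <- make_toy_tiles(n = 60)
  proj <- fit_pixel_pca(tiles, n_components = 10)
  X <- do.call(rbind, lapply(tiles, function(t) as.numeric(unclass(t))))
  total_var <- sum(diag(cov(X)))
  # most of the variance sits on the few generative axes, and the leading
  # eigenvalues agree with the full eigendecomposition oracle
  expect_gt(sum(proj$sdev[1:3]^2) / total_var, 0.6)
  full <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(proj$sdev[1:3]^2, full[1:3], tolerance = 1e-8)
})

test_that("projection has the contracted shape and centers at the mean", {
  tiles <- make_toy_tiles(n = 30)
  proj <- fit_pixel_pca(tiles, n_components = 10)
  scores <- flatten_and_project(tiles, proj)
  expect_equal(dim(scores), c(30, 10))
  # the training-mean tile projects to the origin
  mean_tile <- matrix(proj$mean, 12, 12)
  expect_equal(as.numeric(flatten_and_project(list(mean_tile), proj)),
               rep(0, 10), tolerance = 1e-10)
  # projecting validation tiles uses only training statistics
  val <- make_toy_tiles(n = 5, seed = 99)
  sv <- flatten_and_project(val, proj)
  Xv <- do.call(rbind, lapply(val, function(t) as.numeric(unclass(t))))
  expect_equal(sv, sweep(Xv, 2, proj$mean) %*% proj$rotation)
  expect_error(flatten_and_project(list(matrix(0L, 5, 5)), proj),
               "size mismatch")
})

test_that("every classifier separates linearly separable features", {
  set.seed(10)
  n <- 120
  labels <- rep(c("defective", "non-defective"), each = n / 2)
  feats <- cbind(rnorm(n, ifelse(labels == "defective", 3, -3), 0.3),
                 matrix(rnorm(n * 4), n, 4))
  tab <- run_classifier_suite(feats, labels,
                              split_config(n_repeats = 2, seed = 1))
  expect_equal(tab$accuracy, rep(1, 5))
  expect_equal(tab$f1, rep(1, 5))
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(11)
  n <- 200
  feats <- matrix(rnorm(n * 5), n, 5)
  labels <- sample(rep(c("a", "b"), c(120, 80)))
  tab <- run_classifier_suite(feats, labels,
                              split_config(n_repeats = 3, seed = 2),
                              models = c("sgd_linear", "decision_tree",
                                         "naive_bayes"))
  maj <- 0.6
  n_test <- round(0.15 * n)
  sigma <- sqrt(maj * (1 - maj) / n_test)
  expect_true(all(abs(tab$accuracy - maj) < 3.5 * sigma + 0.05))
})

test_that("the suite is deterministic under a fixed seed and validates input", {
  set.seed(12)
  feats <- matrix(rnorm(60 * 3), 60, 3)
  labels <- rep(c("x", "y"), 30)
  t1 <- run_classifier_suite(feats, labels, split_config(n_repeats = 2, seed = 5),
                             models = c("sgd_linear", "naive_bayes"))
  t2 <- run_classifier_suite(feats, labels, split_config(n_repeats = 2, seed = 5),
                             models = c("sgd_linear", "naive_bayes"))
  expect_identical(t1, t2)
  expect_error(run_classifier_suite(feats, rep("x", 60)), "both classes")
})

test_that("grouped splits keep sibling tiles together", {
  set.seed(13)
  n <- 200
  groups <- rep(sprintf("g%02d", 1:20), each = 10)
  labels <- factor(rep(c("a", "b"), 100))
  cfg <- split_config(seed = 3)
  part <- mnaqc:::with_seed(3, mnaqc:::make_split(labels, cfg, groups))
  for (g in unique(groups)) {
    expect_length(unique(part[groups == g]), 1)
  }
})
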