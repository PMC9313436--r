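make_normal_tile <- function(jitter = 0, seed = NULL) {
  # a rectangular needle silhouette in a 64x64 tile, optionally jittered
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, 64, 64)
  dx <- if (jitter > 0) sample(-jitter:jitter, 1) else 0
  m[20:60, (26 + dx):(38 + dx)] <- 1L
  m[61:64, ] <- 1L
  binary_mask(m)
}

test_that("identical training tiles give zero distance on themselves", {
  tiles <- replicate(20, make_normal_tile(), simplify = FALSE)
  expect_warning(model <- fit_padim(tiles, padim_config()),
                 "fewer training tiles")
  sc <- score_anomaly(tiles[[1]], model)
  expect_lt(sc$image_score, 1e-6)
  expect_true(all(sc$position_scores < 1e-6))
})

test_that("Mahalanobis distances match the closed form", {
  # toy 1-D: mu = 0, sigma^2 = 1, x = 3 -> distance 3
  d <- mnaqc:::position_distances(matrix(3, 1, 1), mu = 0,
                                  cholS = chol(matrix(1, 1, 1)))
  expect_equal(d, 3)
  # 2-D hand-computed sample moments
  X <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3), ncol = 2)
  mu <- colMeans(X); S <- cov(X)
  x <- c(4, 4)
  expect_equal(mnaqc:::position_distances(matrix(x, 1), mu, chol(S)),
               sqrt(mahalanobis(matrix(x, 1), mu, S)))
})

test_that("Mahalanobis scores are invariant to affine feature rescaling", {
  set.seed(20)
  X <- matrix(rnorm(200), 50, 4)
  x0 <- rnorm(4)
  d1 <- mnaqc:::position_distances(matrix(x0, 1), colMeans(X), chol(cov(X)))
  A <- diag(c(2, 0.5, 10, 1))
  Xs <- X %*% A
  d2 <- mnaqc:::position_distances(matrix(x0 %*% A, 1), colMeans(Xs),
                                   chol(cov(Xs)))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("a planted string band is localized by the anomaly map", {
  set.seed(21)
  tiles <- lapply(1:80, function(i) make_normal_tile(jitter = 1))
  model <- fit_padim(tiles, padim_config())
  bad <- make_normal_tile()
  bad[44:46, 1:20] <- 1L   # horizontal string stub entering from the left
  sc <- score_anomaly(bad, model)
  peak <- which(sc$map == max(sc$map), arr.ind = TRUE)[1, ]
  expect_true(peak[1] >= 36 && peak[1] <= 54)
  expect_true(peak[2] <= 28)
  # a defect-free tile scores far lower
  good <- make_normal_tile(jitter = 1)
  expect_gt(sc$image_score, 3 * score_anomaly(good, model)$image_score)
})

test_that("scoring is deterministic and batch scoring matches single calls", {
  set.seed(22)
  tiles <- lapply(1:60, function(i) make_normal_tile(jitter = 1))
  model <- fit_padim(tiles, padim_config())
  probe <- lapply(1:5, function(i) make_normal_tile(jitter = 1))
  single <- vapply(probe, function(t) score_anomaly(t, model)$image_score,
                   numeric(1))
  batch <- score_anomaly_batch(probe, model)$image_scores
  expect_equal(single, batch, tolerance = 1e-10)
  expect_identical(score_anomaly(probe[[1]], model)$map,
                   score_anomaly(probe[[1]], model)$map)
})

test_that("anomaly maps rescale jointly to the 0-255 range", {
  maps <- list(matrix(1:4, 2), matrix(5:8, 2))
  rs <- rescale_anomaly_maps(maps)
  expect_equal(min(rs[[1]]), 0)
  expect_equal(max(rs[[2]]), 255)
  expect_true(all(unlist(rs) >= 0 & unlist(rs) <= 255))
  flat <- rescale_anomaly_maps(list(matrix(2, 3, 3)))
  expect_true(all(flat[[1]] == 0))
})

test_that("ROC-AUC equals exhaustive pair counting", {
  expect_equal(evaluate_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(evaluate_auc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)
  s <- c(0.3, 0.8, 0.8, 0.1); l <- c(0, 1, 0, 1)
  expect_equal(evaluate_auc(s, l), oracle_auc(s, l))
  set.seed(23)
  for (i in 1:10) {
    s <- round(runif(12), 1)
    l <- sample(c(0, 1), 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(evaluate_auc(s, l), oracle_auc(s, l))
  }
  # cross-check against an established implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(24)
    s <- rnorm(50); l <- sample(c(0, 1), 50, replace = TRUE)
    expect_equal(evaluate_auc(s, l),
                 as.numeric(suppressMessages(pROC::auc(l, s,
                                                       direction = "<"))))
  }
  expect_error(evaluate_auc(1:5, rep(1, 5)), "both defective")
})
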