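#' Patch-embedding configuration for anomaly detection
#'
#' Patch-distribution anomaly detection fits one multivariate Gaussian per
#' patch-grid position over patch embeddings of defect-free tiles, then
#' scores new tiles by per-position Mahalanobis distance. Here the embedding
#' is a handcrafted multi-scale patch feature rather than a pretrained CNN:
#' each tile is resized to `working_res` x `working_res` and described by
#' three channels (raw intensity, Gaussian-smoothed intensity, gradient
#' magnitude); the embedding of a grid cell is the concatenation of the three
#' channels' pixels inside the cell. The probabilistic core of the method is
#' unchanged and the embedding is pluggable.
#'
#' @param working_res working resolution in pixels (tiles are resized to
#'   `working_res` x `working_res`).
#' @param cell_px cell side length; the patch grid is
#'   `(working_res / cell_px)^2` positions.
#' @param smooth_sigma sigma of the Gaussian smoothing channel, in working
#'   pixels.
#' @param d_select optional number of randomly selected embedding dimensions
#'   (a dimensionality-reduction device from the original patch-distribution
#'   method); `NULL` keeps the full embedding.
#' @param epsilon_scale covariance shrinkage: `eps = epsilon_scale *
#'   trace(Sigma) / dim` is added to the diagonal.
#' @param seed RNG seed (used only for `d_select`).
#' @export
padim_config <- function(working_res = 64, cell_px = 4, smooth_sigma = 2,
                         d_select = NULL, epsilon_scale = 0.01, seed = 1L) {
  stopifnot(working_res %% cell_px == 0, epsilon_scale >= 0)
  d_full <- 3 * cell_px^2
  if (!is.null(d_select)) stopifnot(d_select <= d_full, d_select >= 1)
  structure(list(working_res = as.integer(working_res),
                 cell_px = as.integer(cell_px),
                 grid = as.integer(working_res / cell_px),
                 smooth_sigma = smooth_sigma,
                 d_full = d_full,
                 d_select = d_select,
                 epsilon_scale = epsilon_scale,
                 seed = as.integer(seed)),
            class = "padim_config")
}

# gradient magnitude by central differences
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]
  gy <- m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2)
}

# embed one tile: returns a (grid^2) x d matrix, positions in column-major
# cell order
embed_tile <- function(tile, cfg) {
  m <- as.matrix(unclass(tile)) * 1.0
  if (!all(dim(m) == cfg$working_res)) {
    m <- as.matrix(EBImage::resize(m, w = cfg$working_res,
                                   h = cfg$working_res))
  }
  sm <- as.matrix(EBImage::gblur(m, sigma = cfg$smooth_sigma))
  gr <- grad_mag(m)
  g <- cfg$grid; cp <- cfg$cell_px
  emb <- matrix(0, g * g, cfg$d_full)
  pos <- 1L
  for (j in seq_len(g)) {
    cols <- ((j - 1) * cp + 1):(j * cp)
    for (i in seq_len(g)) {
      rows <- ((i - 1) * cp + 1):(i * cp)
      emb[pos, ] <- c(m[rows, cols], sm[rows, cols], gr[rows, cols])
      pos <- pos + 1L
    }
  }
  if (!is.null(cfg$dims_kept)) emb <- emb[, cfg$dims_kept, drop = FALSE]
  emb
}

#' Fit the normal-class patch-Gaussian model
#'
#' Single-pass moment estimation: for every patch-grid position, the sample
#' mean and covariance of the embeddings of the defect-free training tiles,
#' with diagonal shrinkage `eps = epsilon_scale * trace(Sigma)/d`. There is
#' no iterative training loop.
#'
#' @param tiles list of defect-free tiles ([binary_mask()]s or matrices).
#' @param cfg a [padim_config()].
#' @return a `padim_model`: per-position means and Cholesky factors of the
#'   regularized covariances.
#' @export
fit_padim <- function(tiles, cfg = padim_config()) {
  if (length(tiles) == 0) stop("empty training set")
  if (!is.null(cfg$d_select)) {
    cfg$dims_kept <- with_seed(cfg$seed,
                               sort(sample(cfg$d_full, cfg$d_select)))
  }
  d <- if (is.null(cfg$d_select)) cfg$d_full else cfg$d_select
  if (length(tiles) <= d) {
    warning("fewer training tiles (", length(tiles), ") than embedding ",
            "dimension (", d, "); relying on shrinkage regularization")
  }
  n_pos <- cfg$grid^2
  embs <- array(0, dim = c(length(tiles), n_pos, d))
  for (t in seq_along(tiles)) embs[t, , ] <- embed_tile(tiles[[t]], cfg)
  means <- matrix(0, n_pos, d)
  chols <- vector("list", n_pos)
  for (p in seq_len(n_pos)) {
    X <- embs[, p, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = length(tiles))
    mu <- colMeans(X)
    S <- stats::cov(X)
    S[is.na(S)] <- 0
    eps <- cfg$epsilon_scale * sum(diag(S)) / d
    if (eps <= 0) eps <- 1e-6
    chols[[p]] <- chol(S + diag(eps, d))
    means[p, ] <- mu
  }
  structure(list(cfg = cfg, means = means, chols = chols, d = d,
                 n_train = length(tiles)),
            class = "padim_model")
}

# Mahalanobis distances for a stack of embeddings at one position
position_distances <- function(X, mu, cholS) {
  Z <- forwardsolve(t(cholS), t(sweep(X, 2, mu)))
  sqrt(colSums(Z^2))
}

#' Score a tile against the fitted normal model
#'
#' Per-position Mahalanobis distance `sqrt((x-mu)' (Sigma+eps I)^-1 (x-mu))`,
#' upsampled to the tile resolution and Gaussian-smoothed into an anomaly
#' map. The image-level score is the maximum raw (pre-smoothing,
#' pre-rescaling) position distance. Maps from a whole dataset are rescaled
#' jointly to 0--255 with [rescale_anomaly_maps()] so intensities are
#' comparable across tiles.
#'
#' @param tile a tile mask or matrix.
#' @param model a `padim_model` from [fit_padim()].
#' @param map_size side length of the returned map (default: the tile's own
#'   size).
#' @return a list of class `anomaly_map`: `map` (smoothed raw distances at
#'   `map_size` resolution), `position_scores` (grid x grid matrix) and
#'   `image_score`.
#' @export
score_anomaly <- function(tile, model, map_size = NULL) {
  if (!inherits(model, "padim_model")) stop("`model` must be a fitted padim_model")
  cfg <- model$cfg
  emb <- embed_tile(tile, cfg)
  n_pos <- cfg$grid^2
  dist <- numeric(n_pos)
  for (p in seq_len(n_pos)) {
    dist[p] <- position_distances(matrix(emb[p, ], 1), model$means[p, ],
                                  model$chols[[p]])
  }
  pos <- matrix(dist, cfg$grid, cfg$grid)   # column-major cell order
  if (is.null(map_size)) {
    map_size <- if (is.matrix(tile) || is_binary_mask(tile)) nrow(tile) else
      cfg$working_res
  }
  up <- as.matrix(EBImage::resize(pos, w = map_size, h = map_size))
  up <- as.matrix(EBImage::gblur(up, sigma = max(2, map_size / 37.5)))
  structure(list(map = up, position_scores = pos, image_score = max(dist)),
            class = "anomaly_map")
}

#' Score many tiles efficiently
#'
#' Vectorizes [score_anomaly()] across tiles (solving each position's
#' triangular system once for the whole stack) and returns image-level
#' scores; per-tile maps are optional.
#'
#' @param tiles list of tiles.
#' @param model a `padim_model`.
#' @param maps return per-tile anomaly maps as well (memory permitting).
#' @return a list with `image_scores` (numeric) and, when requested, `maps`.
#' @export
score_anomaly_batch <- function(tiles, model, maps = FALSE) {
  cfg <- model$cfg
  n <- length(tiles); n_pos <- cfg$grid^2
  embs <- array(0, dim = c(n, n_pos, model$d))
  for (t in seq_len(n)) embs[t, , ] <- embed_tile(tiles[[t]], cfg)
  dists <- matrix(0, n, n_pos)
  for (p in seq_len(n_pos)) {
    X <- matrix(embs[, p, ], nrow = n)
    dists[, p] <- position_distances(X, model$means[p, ], model$chols[[p]])
  }
  out <- list(image_scores = apply(dists, 1, max))
  if (maps) {
    out$maps <- lapply(seq_len(n), function(t) {
      pos <- matrix(dists[t, ], cfg$grid, cfg$grid)
      ms <- nrow(as.matrix(unclass(tiles[[t]])))
      up <- as.matrix(EBImage::resize(pos, w = ms, h = ms))
      as.matrix(EBImage::gblur(up, sigma = max(2, ms / 37.5)))
    })
  }
  out
}

#' Jointly rescale anomaly maps to 8-bit intensities
#'
#' Min-max rescales a set of raw anomaly maps to 0--255 using the pooled
#' range (0 = no anomaly, 255 = strongest anomaly in the set), so pixel
#' intensities are comparable across tiles of one report.
#'
#' @param maps list of numeric matrices.
#' @return list of integer matrices on 0--255.
#' @export
rescale_anomaly_maps <- function(maps) {
  lo <- min(vapply(maps, min, numeric(1)))
  hi <- max(vapply(maps, max, numeric(1)))
  if (hi <= lo) return(lapply(maps, function(m) m * 0L))
  lapply(maps, function(m) {
    matrix(as.integer(round(255 * (m - lo) / (hi - lo))), nrow(m), ncol(m))
  })
}

#' Image-level ROC-AUC by the rank statistic
#'
#' The probability that a randomly chosen defective tile receives a higher
#' anomaly score than a randomly chosen non-defective one, with ties counted
#' as one half (the Wilcoxon-Mann-Whitney estimator of the area under the
#' ROC curve).
#'
#' @param scores numeric anomaly scores.
#' @param labels logical or 0/1: `TRUE`/1 marks defective.
#' @return the AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both defective and non-defective scores")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
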