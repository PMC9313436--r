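#' Principal-component projection of flattened tile pixels
#'
#' Fits a PCA basis on flattened single-needle tiles (a 150 x 150 tile
#' becomes a 22,500-vector) to reduce the pixel space to a handful of
#' components before classical classification. Because the number of tiles n
#' is far below the pixel count p, the fit uses the n x n Gram-matrix
#' eigendecomposition rather than the p x p covariance; the recovered
#' components are orthonormal and identical to the direct eigenvectors up to
#' sign. Fit the projection on the training split only.
#'
#' @param tiles list of equal-sized [binary_mask()]s (or numeric matrices).
#' @param n_components number of components to keep (default 10).
#' @return an object of class `pixel_pca` with elements `mean` (length-p
#'   vector), `rotation` (p x k orthonormal matrix), `sdev`, and `dim` (tile
#'   dimensions).
#' @export
fit_pixel_pca <- function(tiles, n_components = 10) {
  X <- flatten_tiles(tiles)
  n <- nrow(X); p <- ncol(X)
  k <- min(n_components, n - 1, p)
  if (k < 1) stop("need at least 2 tiles to fit a projection")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  G <- tcrossprod(Xc)                    # n x n
  eg <- eigen(G, symmetric = TRUE)
  pos <- which(eg$values > 1e-9 * max(eg$values, 1e-12))
  k <- min(k, length(pos))
  if (k < 1) stop("tiles are all identical: no principal components")
  lam <- eg$values[seq_len(k)]
  rotation <- crossprod(Xc, eg$vectors[, seq_len(k), drop = FALSE])
  rotation <- sweep(rotation, 2, sqrt(lam), "/")
  structure(list(mean = mu, rotation = rotation,
                 sdev = sqrt(lam / (n - 1)),
                 total_var = sum(eg$values[pos]) / (n - 1),
                 dim = dim(as.matrix(unclass(tiles[[1]])))),
            class = "pixel_pca")
}

flatten_tiles <- function(tiles) {
  if (is.matrix(tiles) && !is.list(tiles)) return(tiles)
  do.call(rbind, lapply(tiles, function(t) as.numeric(unclass(t))))
}

#' Project tiles onto a fitted pixel-PCA basis
#'
#' @param tiles list of tiles with the same dimensions the projection was
#'   fitted on.
#' @param proj a `pixel_pca` from [fit_pixel_pca()].
#' @return an n x k score matrix (centered, projected).
#' @export
flatten_and_project <- function(tiles, proj) {
  X <- flatten_tiles(tiles)
  if (ncol(X) != length(proj$mean)) {
    stop("tile size mismatch: projection was fitted on ",
         paste(proj$dim, collapse = "x"), " tiles")
  }
  sweep(X, 2, proj$mean) %*% proj$rotation
}

#' Train/validation/test split configuration
#'
#' @param train_frac,val_frac,test_frac split fractions; must sum to 1.
#' @param n_repeats number of random re-splits over which scores are
#'   averaged.
#' @param seed RNG seed.
#' @export
split_config <- function(train_frac = 0.75, val_frac = 0.10,
                         test_frac = 0.15, n_repeats = 5, seed = 1L) {
  stopifnot(abs(train_frac + val_frac + test_frac - 1) < 1e-8,
            n_repeats >= 1)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_config")
}

# stratified (and optionally group-respecting) assignment of indices to
# train/val/test; groups keep all tiles of one source array together, and a
# group's stratum is its majority label
make_split <- function(labels, cfg, groups = NULL) {
  n <- length(labels)
  assign <- character(n)
  fracs <- c(train = cfg$train_frac, val = cfg$val_frac, test = cfg$test_frac)
  if (is.null(groups)) groups <- seq_len(n)
  gl <- split(seq_len(n), groups)
  strata <- vapply(gl, function(idx) {
    names(which.max(table(labels[idx])))
  }, character(1))
  for (s in unique(strata)) {
    gs <- sample(names(gl)[strata == s])
    total <- sum(lengths(gl[gs]))
    # greedy: feed groups to the split with the largest remaining deficit
    target <- fracs * total
    got <- c(train = 0, val = 0, test = 0)
    for (g in gs) {
      pick <- names(which.max(target - got))
      assign[gl[[g]]] <- pick
      got[pick] <- got[pick] + length(gl[[g]])
    }
  }
  assign
}

classifier_families <- function() {
  list(
    sgd_linear = list(
      grid = list(NULL),
      fit = function(x, y, hp) {
        suppressWarnings(stats::glm.fit(cbind(1, x), y == levels(y)[2],
                                        family = stats::binomial()))
      },
      predict = function(fit, x, lev) {
        eta <- cbind(1, x) %*% fit$coefficients
        factor(lev[(eta > 0) + 1], levels = lev)
      }
    ),
    decision_tree = list(
      grid = list(list(cp = 0.01), list(cp = 0.001)),
      fit = function(x, y, hp) {
        df <- data.frame(y = y, x)
        rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(cp = hp$cp, xval = 0))
      },
      predict = function(fit, x, lev) {
        stats::predict(fit, data.frame(x), type = "class")
      }
    ),
    naive_bayes = list(
      grid = list(NULL),
      fit = function(x, y, hp) e1071::naiveBayes(x, y),
      predict = function(fit, x, lev) stats::predict(fit, x)
    ),
    mlp = list(
      grid = list(list(decay = 0.1), list(decay = 0.01)),
      fit = function(x, y, hp) {
        nnet::nnet(x, stats::model.matrix(~ y - 1), size = 100,
                   decay = hp$decay, maxit = 200, trace = FALSE,
                   softmax = TRUE, MaxNWts = 1e5)
      },
      predict = function(fit, x, lev) {
        factor(lev[max.col(stats::predict(fit, x))], levels = lev)
      }
    ),
    svm = list(
      grid = list(list(cost = 1), list(cost = 10)),
      fit = function(x, y, hp) e1071::svm(x, y, kernel = "radial",
                                          cost = hp$cost),
      predict = function(fit, x, lev) stats::predict(fit, x)
    )
  )
}

macro_report <- function(truth, pred) {
  lev <- levels(truth)
  per <- lapply(lev, function(l) {
    tp <- sum(pred == l & truth == l); fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  m <- colMeans(do.call(rbind, per))
  c(m, accuracy = mean(pred == truth))
}

#' Run the classical classifier suite
#'
#' Trains each model family on stratified random 75/10/15
#' train/validation/test splits, uses the validation split to pick within
#' each family's small hyperparameter grid, scores the test split, and
#' averages over `n_repeats` re-splits. Precision/recall/F1 are
#' macro-averaged over the two classes.
#'
#' @param features numeric matrix (e.g. PCA scores from
#'   [flatten_and_project()]).
#' @param labels factor or vector coercible to a 2-level factor.
#' @param split a [split_config()].
#' @param models subset of `c("sgd_linear", "decision_tree", "naive_bayes",
#'   "mlp", "svm")`.
#' @param groups optional grouping vector (e.g. source array id); all
#'   members of a group land in the same split to prevent leakage between
#'   sibling needles.
#' @return a data.frame with one row per model: mean and sd of precision,
#'   recall, F1 and accuracy over the repeats.
#' @export
run_classifier_suite <- function(features, labels, split = split_config(),
                                 models = c("sgd_linear", "decision_tree",
                                            "naive_bayes", "mlp", "svm"),
                                 groups = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need both classes present")
  features <- as.matrix(features)
  fams <- classifier_families()[models]
  res <- array(NA_real_, dim = c(length(models), 4, split$n_repeats),
               dimnames = list(models,
                               c("precision", "recall", "f1", "accuracy"),
                               NULL))
  with_seed(split$seed, {
    for (rep in seq_len(split$n_repeats)) {
      part <- make_split(labels, split, groups)
      tr <- part == "train"; va <- part == "val"; te <- part == "test"
      lev <- levels(labels)
      for (m in models) {
        fam <- fams[[m]]
        # validation split selects within the family's grid
        best <- NULL
        for (hp in fam$grid) {
          fit <- fam$fit(features[tr, , drop = FALSE], labels[tr], hp)
          acc <- if (length(fam$grid) > 1 && sum(va) > 0) {
            mean(fam$predict(fit, features[va, , drop = FALSE], lev) ==
                   labels[va])
          } else 0
          if (is.null(best) || acc > best$acc) best <- list(fit = fit,
                                                            acc = acc)
        }
        pred <- fam$predict(best$fit, features[te, , drop = FALSE], lev)
        res[m, , rep] <- macro_report(labels[te], pred)
      }
    }
  })
  out <- data.frame(model = models)
  for (stat in dimnames(res)[[2]]) {
    out[[stat]] <- apply(res[, stat, , drop = FALSE], 1, mean)
    out[[paste0(stat, "_sd")]] <- apply(res[, stat, , drop = FALSE], 1,
                                        stats::sd)
  }
  rownames(out) <- NULL
  out
}
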