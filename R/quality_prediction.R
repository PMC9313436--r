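#' Validated input ranges for the quality predictor
#'
#' Closed intervals each of the five predictor features must lie in before a
#' prediction is served. The concentration interval is physically grounded
#' (below 3 M KOH etches too slowly; 21.6 M is the solubility limit in water
#' at 25 C); the remaining intervals are configurable plausibility bounds.
#'
#' @param base_diameter_um,height_um,draft_angle_deg,concentration_m,duration_h
#'   length-2 numeric `c(lower, upper)` intervals.
#' @return a data.frame with columns `feature`, `lower`, `upper`.
#' @export
input_ranges <- function(base_diameter_um = c(100, 3000),
                         height_um = c(100, 5000),
                         draft_angle_deg = c(0, 15),
                         concentration_m = c(3, 21.6),
                         duration_h = c(0, 48)) {
  rng <- list(base_diameter_um = base_diameter_um, height_um = height_um,
              draft_angle_deg = draft_angle_deg,
              concentration_m = concentration_m, duration_h = duration_h)
  for (nm in names(rng)) {
    if (rng[[nm]][1] >= rng[[nm]][2]) stop("invalid range for ", nm)
  }
  data.frame(feature = names(rng),
             lower = vapply(rng, `[`, numeric(1), 1),
             upper = vapply(rng, `[`, numeric(1), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

quality_features <- c("base_diameter_um", "height_um", "draft_angle_deg",
                      "concentration_m", "duration_h")

regression_families <- function() {
  list(
    linear = list(
      fit = function(x, y) stats::lm.fit(cbind(1, x), y),
      predict = function(fit, x) drop(cbind(1, x) %*% fit$coefficients)
    ),
    regression_tree = list(
      fit = function(x, y) rpart::rpart(y ~ ., data.frame(y = y, x),
                                        method = "anova",
                                        control = rpart::rpart.control(
                                          cp = 0.001, xval = 0)),
      predict = function(fit, x) stats::predict(fit, data.frame(x))
    ),
    svm = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "radial"),
      predict = function(fit, x) stats::predict(fit, x)
    ),
    gaussian_process_sqexp = list(
      # fixed squared-exponential scale on standardized features (the median
      # heuristic for ~5 standardized dimensions gives sigma ~ 0.1)
      fit = function(x, y) kernlab::gausspr(x, y,
                                            kernel = kernlab::rbfdot(sigma = 0.1),
                                            var = 0.001),
      predict = function(fit, x) drop(kernlab::predict(fit, x))
    ),
    neural_net = list(
      fit = function(x, y) nnet::nnet(x, y, size = 8, decay = 0.01,
                                      linout = TRUE, maxit = 500,
                                      trace = FALSE),
      predict = function(fit, x) drop(stats::predict(fit, x))
    )
  )
}

#' Per-metric regression with 5-fold cross-validation
#'
#' For each similarity metric, fits every regression family (linear,
#' regression tree, SVM, squared-exponential Gaussian process, neural
#' network) on the five fabrication features under k-fold cross-validation.
#' Each validation fold yields `R^2 = 1 - SS_res/SS_tot` (total sum of
#' squares about the fold's own mean); the reported value is the arithmetic
#' mean of the fold values, never a pooled fit, and the best family is the
#' one with the highest mean R^2. Features are standardized with training-
#' fold statistics before fitting (scale-sensitive families need it; the
#' others are unaffected).
#'
#' @param table data.frame holding the five feature columns
#'   (`base_diameter_um`, `height_um`, `draft_angle_deg`,
#'   `concentration_m`, `duration_h`) and the metric columns.
#' @param metrics metric column names to regress.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return a list of class `regression_report`: per metric, a data.frame of
#'   per-family mean and per-fold R^2, plus `best` naming the winning family.
#' @export
fit_metric_regressions <- function(table,
                                   metrics = c("similarity_index",
                                               "area_ratio", "accuracy",
                                               "sensitivity", "dice"),
                                   folds = 5, seed = 1L) {
  stopifnot(all(quality_features %in% names(table)),
            all(metrics %in% names(table)), nrow(table) >= folds)
  X <- as.matrix(table[quality_features])
  fams <- regression_families()
  fold_id <- with_seed(seed, sample(rep(seq_len(folds),
                                        length.out = nrow(table))))
  out <- list()
  for (metric in metrics) {
    y <- table[[metric]]
    if (stats::var(y) == 0) {
      stop("metric `", metric, "` is constant: R^2 undefined")
    }
    fam_r2 <- matrix(NA_real_, length(fams), folds,
                     dimnames = list(names(fams), NULL))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      for (fam in names(fams)) {
        fit <- with_seed(seed + f, fams[[fam]]$fit(Xs[tr, , drop = FALSE],
                                                   y[tr]))
        pred <- fams[[fam]]$predict(fit, Xs[!tr, , drop = FALSE])
        ss_res <- sum((y[!tr] - pred)^2)
        ss_tot <- sum((y[!tr] - mean(y[!tr]))^2)
        fam_r2[fam, f] <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      }
    }
    mean_r2 <- rowMeans(fam_r2)
    out[[metric]] <- list(
      r2 = data.frame(family = names(fams), mean_r2 = mean_r2,
                      row.names = NULL, stringsAsFactors = FALSE),
      fold_r2 = fam_r2,
      best = names(fams)[which.max(mean_r2)],
      best_r2 = max(mean_r2)
    )
  }
  structure(out, class = "regression_report")
}

#' Quality labeler
#'
#' @param metric metric column the label is derived from.
#' @param threshold values at or above the threshold are Class 1 (accepted
#'   quality); values below are Class 0 (low quality).
#' @export
quality_labeler <- function(metric = "sensitivity", threshold = 0.8) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(metric = metric, threshold = threshold),
            class = "quality_labeler")
}

#' Binarize a similarity metric into quality classes
#'
#' @param table data.frame containing the labeler's metric column, values in
#'   `[0, 1]`.
#' @param labeler a [quality_labeler()].
#' @return integer vector of 0/1 labels (1 = accepted quality; the threshold
#'   value itself is Class 1).
#' @export
binarize_quality <- function(table, labeler = quality_labeler()) {
  x <- table[[labeler$metric]]
  if (is.null(x)) stop("column `", labeler$metric, "` not found")
  if (any(x < 0 | x > 1)) {
    stop("`", labeler$metric, "` values outside [0, 1]")
  }
  as.integer(x >= labeler$threshold)
}

# fit a full tree and prune it so the number of internal splits is <= m
fit_pruned_tree <- function(x, y, criterion, max_splits, final = FALSE) {
  parms <- list(split = if (criterion == "gini") "gini" else "information")
  ctl <- rpart::rpart.control(cp = 0, xval = 0, minsplit = 4, minbucket = 2,
                              maxcompete = 0, maxsurrogate = 0)
  df <- data.frame(y = factor(y, levels = c(0, 1)), x)
  fit <- rpart::rpart(y ~ ., df, method = "class", parms = parms,
                      control = ctl)
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  if (!any(ok)) return(NULL)
  cp_target <- cpt[max(which(ok)), "CP"]
  rpart::prune(fit, cp = cp_target + 1e-12)
}

#' Optimize the quality classification tree
#'
#' Grid-searches the two tree hyperparameters -- maximum number of splits
#' (1..50) and split criterion (Gini diversity index vs cross-entropy /
#' information) -- by k-fold cross-validated accuracy, breaking ties toward
#' fewer splits and then toward Gini, and refits the winning configuration
#' on all data.
#'
#' @param features data.frame or matrix of the five fabrication features.
#' @param labels 0/1 quality labels (both classes must be present).
#' @param max_splits_grid candidate values for the maximum split count.
#' @param criteria candidate split criteria.
#' @param folds CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return a `tree_model`: the refit `rpart` tree, the winning
#'   hyperparameters, the CV accuracy surface, and the pooled-CV accuracy of
#'   the winner.
#' @export
optimize_tree <- function(features, labels, max_splits_grid = 1:50,
                          criteria = c("gini", "cross_entropy"),
                          folds = 5, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need both quality classes present")
  x <- as.data.frame(features)
  n <- length(labels)
  folds <- max(2, min(folds, floor(n / 2)))
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  acc <- array(NA_real_,
               dim = c(length(max_splits_grid), length(criteria), folds),
               dimnames = list(max_splits_grid, criteria, NULL))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(labels[tr])) < 2) next
    for (crit in criteria) {
      full <- fit_pruned_tree(x[tr, , drop = FALSE], labels[tr], crit,
                              max(max_splits_grid))
      if (is.null(full)) next
      cpt <- full$cptable
      for (mi in seq_along(max_splits_grid)) {
        ok <- cpt[, "nsplit"] <= max_splits_grid[mi]
        if (!any(ok)) next
        pr <- rpart::prune(full, cp = cpt[max(which(ok)), "CP"] + 1e-12)
        pred <- stats::predict(pr, x[!tr, , drop = FALSE], type = "class")
        acc[mi, crit, f] <- mean(as.integer(as.character(pred)) ==
                                   labels[!tr])
      }
    }
  }
  cv_acc <- suppressWarnings(apply(acc, c(1, 2), mean, na.rm = TRUE))
  if (!any(is.finite(cv_acc))) {
    # data too small for any CV fold to carry both classes: fall back to a
    # default configuration rather than failing
    best_splits <- min(20, max(max_splits_grid))
    best_crit <- criteria[1]
    best_acc <- NA_real_
  } else {
    # ties toward fewer splits, then gini (column order)
    best <- which(cv_acc == max(cv_acc, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    best_splits <- max_splits_grid[best[1]]
    best_crit <- criteria[best[2]]
    best_acc <- max(cv_acc, na.rm = TRUE)
  }
  final <- fit_pruned_tree(x, labels, best_crit, best_splits, final = TRUE)
  structure(list(tree = final, max_splits = best_splits,
                 criterion = best_crit, cv_accuracy = cv_acc,
                 best_cv_accuracy = best_acc,
                 folds = folds, seed = seed,
                 feature_names = names(x)),
            class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf(paste0("<tree_model: criterion=%s, max_splits=%d, ",
                     "CV accuracy=%.3f>\n"),
              x$criterion, x$max_splits, x$best_cv_accuracy))
  invisible(x)
}

#' Cross-validated confusion matrix of a tree model
#'
#' Refits the model's winning hyperparameters within each CV fold, pools the
#' held-out predictions into one 2x2 confusion matrix (rows = true class,
#' columns = predicted class, class 0 first), and derives
#' accuracy/sensitivity/specificity via [compute_classification_report()]
#' with Class 1 (accepted quality) as the positive class. A held-out variant
#' is available for auditing.
#'
#' @param model a `tree_model` from [optimize_tree()].
#' @param features,labels the data to evaluate on.
#' @param folds CV folds.
#' @param seed fold-assignment seed.
#' @param method `"cv_pooled"` (default) or `"holdout"` (single stratified
#'   75/25 split).
#' @return list with `confusion` (2x2 matrix) and `report`
#'   (a `classification_report`).
#' @export
evaluate_tree <- function(model, features, labels, folds = 5, seed = 1L,
                          method = c("cv_pooled", "holdout")) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  x <- as.data.frame(features)
  n <- length(labels)
  pred <- rep(NA_integer_, n)
  if (method == "cv_pooled") {
    fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_pruned_tree(x[tr, , drop = FALSE], labels[tr],
                             model$criterion, model$max_splits)
      p <- stats::predict(fit, x[!tr, , drop = FALSE], type = "class")
      pred[!tr] <- as.integer(as.character(p))
    }
  } else {
    te <- with_seed(seed, {
      idx <- logical(n)
      for (l in unique(labels)) {
        il <- which(labels == l)
        idx[sample(il, round(0.25 * length(il)))] <- TRUE
      }
      idx
    })
    fit <- fit_pruned_tree(x[!te, , drop = FALSE], labels[!te],
                           model$criterion, model$max_splits)
    pred[te] <- as.integer(as.character(
      stats::predict(fit, x[te, , drop = FALSE], type = "class")))
    labels <- labels[te]; pred <- pred[te]
  }
  confusion <- table(factor(labels, levels = c(0, 1)),
                     factor(pred, levels = c(0, 1)))
  dimnames(confusion) <- list(true = c("0", "1"), predicted = c("0", "1"))
  report <- compute_classification_report(tp = confusion["1", "1"],
                                          tn = confusion["0", "0"],
                                          fp = confusion["0", "1"],
                                          fn = confusion["1", "0"])
  list(confusion = unclass(confusion), report = report)
}

#' Predict fabrication quality for a new parameter set
#'
#' Validates the five features against their ranges and serves the tree's
#' prediction as `"High"` (Class 1) or `"Low"` (Class 0). Out-of-range
#' inputs are rejected with the offending feature and its valid interval.
#'
#' @param x named numeric vector or one-row data.frame with
#'   `base_diameter_um`, `height_um`, `draft_angle_deg`, `concentration_m`,
#'   `duration_h`.
#' @param model a `tree_model`.
#' @param ranges an [input_ranges()] table.
#' @return `"High"` or `"Low"`.
#' @examples
#' \dontrun{
#' predict_quality(c(base_diameter_um = 1500, height_um = 2000,
#'                   draft_angle_deg = 5, concentration_m = 5,
#'                   duration_h = 14), model)
#' }
#' @export
predict_quality <- function(x, model, ranges = input_ranges()) {
  if (is.data.frame(x)) x <- unlist(x[1, quality_features])
  missing <- setdiff(quality_features, names(x))
  if (length(missing)) stop("missing features: ",
                            paste(missing, collapse = ", "))
  for (i in seq_len(nrow(ranges))) {
    f <- ranges$feature[i]
    if (x[[f]] < ranges$lower[i] || x[[f]] > ranges$upper[i]) {
      stop(sprintf("%s = %g rejected: valid interval is [%g, %g]",
                   f, x[[f]], ranges$lower[i], ranges$upper[i]))
    }
  }
  df <- as.data.frame(as.list(x[quality_features]))
  cls <- as.integer(as.character(
    stats::predict(model$tree, df, type = "class")))
  if (cls == 1L) "High" else "Low"
}

#' Serialize a tree model to portable JSON
#'
#' Writes the fitted tree as nested nodes (`feature`, `threshold`,
#' `left`/`right` children taken when the feature is below / at-or-above the
#' threshold, `class` at leaves) so the predictor can be served without R's
#' model objects.
#'
#' @param model a `tree_model`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
tree_to_json <- function(model, path = NULL) {
  fit <- model$tree
  frame <- fit$frame
  node_ids <- as.integer(rownames(frame))
  splits <- fit$splits
  split_row <- 0L
  build <- local({
    split_of <- integer(0)
    # rpart stores one split row per internal node, in frame order, when
    # maxcompete = maxsurrogate = 0
    k <- 0L
    for (i in seq_along(node_ids)) {
      if (frame$var[i] != "<leaf>") {
        k <- k + 1L
        split_of[as.character(node_ids[i])] <- k
      }
    }
    function(id) {
      i <- match(id, node_ids)
      if (frame$var[i] == "<leaf>") {
        list(leaf = TRUE, class = c(0L, 1L)[frame$yval[i]])
      } else {
        s <- splits[split_of[[as.character(id)]], ]
        thr <- unname(s["index"])
        lo <- Recall(2L * id)
        hi <- Recall(2L * id + 1L)
        # rpart ncat = -1: the first (left) child takes values < threshold;
        # ncat = +1: it takes values >= threshold. JSON always encodes
        # left = "< threshold", so swap when needed.
        if (unname(s["ncat"]) > 0) { tmp <- lo; lo <- hi; hi <- tmp }
        list(leaf = FALSE,
             feature = as.character(frame$var[i]),
             threshold = thr,
             left = lo,
             right = hi)
      }
    }
  })
  obj <- list(type = "classification_tree",
              criterion = model$criterion,
              max_splits = model$max_splits,
              features = model$feature_names,
              root = build(1L))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a JSON-serialized tree
#'
#' @param x named feature vector.
#' @param json a JSON string or file path from [tree_to_json()].
#' @return predicted class (0 or 1).
#' @export
predict_tree_json <- function(x, json) {
  obj <- if (file.exists(json)) jsonlite::fromJSON(json,
                                                   simplifyVector = FALSE)
  else jsonlite::fromJSON(as.character(json), simplifyVector = FALSE)
  node <- obj$root
  while (!isTRUE(node$leaf)) {
    node <- if (x[[node$feature]] < node$threshold) node$left else node$right
  }
  as.integer(node$class)
}

#' Planted-rule quality labels for the factorial
#'
#' Synthetic ground truth for validating the tree-optimization protocol:
#' quality is a known threshold rule on the etch dose (concentration x
#' duration, in M h) whose cutoff depends on the needle-height group
#' (taller designs tolerate less dose before over-etching), with optional
#' independent label noise.
#'
#' @param conditions data.frame from [condition_grid()].
#' @param noise_rate probability that a label is flipped.
#' @param seed RNG seed.
#' @param cutoff_short,cutoff_tall dose cutoffs (M h) below which quality is
#'   accepted, for heights below / at-or-above `tall_height_um`.
#' @param tall_height_um height separating the two groups.
#' @return integer 0/1 labels (1 = accepted quality).
#' @export
planted_quality_labels <- function(conditions, noise_rate = 0.05, seed = 1L,
                                   cutoff_short = 50, cutoff_tall = 42,
                                   tall_height_um = 2500) {
  dose <- conditions$concentration_m * conditions$duration_h
  cutoff <- ifelse(conditions$height_um >= tall_height_um, cutoff_tall,
                   cutoff_short)
  labels <- as.integer(dose <= cutoff)
  if (noise_rate > 0) {
    flip <- with_seed(seed, stats::runif(length(labels)) < noise_rate)
    labels[flip] <- 1L - labels[flip]
  }
  labels
}

#' Smooth synthetic similarity-metric surfaces
#'
#' Generates a metrics table over the factorial whose sensitivity rises to an
#' optimum at mild etch dose (imperfections removed) and falls beyond it
#' (needle material eroded), with congruent surfaces for the other four
#' metrics and additive Gaussian noise. Used to exercise the regression and
#' binarization stages under a known generative model.
#'
#' @param conditions data.frame from [condition_grid()].
#' @param noise_sd standard deviation of the additive noise.
#' @param seed RNG seed.
#' @return the conditions data.frame extended with the five metric columns.
#' @export
simulate_metric_table <- function(conditions, noise_sd = 0.02, seed = 1L) {
  q <- conditions$concentration_m * conditions$duration_h
  aspect <- conditions$height_um / conditions$base_diameter_um
  opt <- 55 - 5 * (aspect - 2)               # taller needles peak earlier
  sens0 <- 0.97 - 0.35 * ((q - opt) / 80)^2 -
    0.02 * (conditions$draft_angle_deg / 10)
  with_seed(seed, {
    n <- nrow(conditions)
    sens <- pmin(1, pmax(0, sens0 + stats::rnorm(n, 0, noise_sd)))
    fp_frac <- pmax(0, 0.25 - 0.004 * q) +
      pmax(0, stats::rnorm(n, 0, noise_sd / 2))
    out <- conditions
    out$sensitivity <- sens
    out$similarity_index <- sens - fp_frac
    out$area_ratio <- sens + fp_frac
    out$accuracy <- pmin(1, 0.9 + 0.1 * sens -
                           0.02 * fp_frac + stats::rnorm(n, 0, noise_sd / 4))
    out$dice <- pmin(1, pmax(0, sens / (1 + fp_frac) +
                               stats::rnorm(n, 0, noise_sd / 2)))
    out
  })
}
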