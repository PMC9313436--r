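#' Default end-to-end run configuration
#'
#' The configuration is a plain nested list (serializable as YAML) with four
#' required blocks: `geometry` (scale and array layout), `fabrication`
#' (print artifacts and etch rate), `pipeline` (tiling and binarization),
#' and `modeling` (seeds, folds, quality threshold, optional stages). Every
#' random seed is explicit.
#'
#' @param seed master seed copied into every stage's seed.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    geometry = list(microns_per_pixel = 25, tile_size = 150,
                    pitch_um = 2500, base_strip_um = 250, n_needles = 10),
    fabrication = list(dilation_um = 0, p_string = 0.7,
                       string_thickness_um = 40, p_defect = 0.15,
                       roughness_sigma_um = 10,
                       etch_rate_um_per_mh = 0.2667, seed = seed),
    pipeline = list(binarize_method = "otsu", align_method = "xcorr"),
    modeling = list(folds = 5, seed = seed, quality_threshold = 0.8,
                    run_anomaly = FALSE, anomaly_train_count = 450,
                    run_classifiers = FALSE, n_components = 10,
                    n_repeats = 5)
  ), class = "run_config")
}

#' Load and validate a run configuration from YAML
#'
#' @param path YAML file with the blocks of [default_run_config()]; missing
#'   leaf values fall back to the defaults, but all four blocks must be
#'   present.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname load_run_config
#' @param config a config list to validate/complete.
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  for (block in names(def)) {
    if (is.null(config[[block]])) {
      stop("config is missing required block `", block, "`")
    }
    for (key in names(def[[block]])) {
      if (is.null(config[[block]][[key]])) {
        config[[block]][[key]] <- def[[block]][[key]]
      }
    }
  }
  g <- config$geometry
  stopifnot(g$microns_per_pixel > 0, g$tile_size >= 1, g$pitch_um > 0)
  structure(config[names(def)], class = "run_config")
}

#' Run the full quality-control pipeline
#'
#' Executes the stages in order for every fabrication condition: render CAD
#' array, simulate print and etch, split into single-needle tiles, align the
#' fabricated array to its CAD reference, count pixel agreement, and compute
#' the five similarity metrics. Then binarizes the sensitivity metric into
#' quality classes and, when both classes are present, optimizes and
#' evaluates the classification tree. Optional stages (config `modeling`
#' block) run the tile classifier suite and the anomaly detector. Artifacts
#' are written under `out_dir` when given; results are also returned.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param conditions condition grid; defaults to the full study factorial.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param keep_tiles keep the per-needle tiles and labels in the returned
#'   object (needed for the optional stages; on the full factorial this
#'   holds 2400 tiles in memory).
#' @return a list with `metrics` (one row per condition: confusion counts
#'   and the five metrics), `labels`, `tree` (a `tree_model` or `NULL`),
#'   `tree_eval`, and optionally `tiles`, `tile_labels`, `classifier_table`,
#'   `anomaly`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         conditions = condition_grid(),
                         out_dir = NULL, keep_tiles = FALSE) {
  config <- validate_run_config(config)
  g <- config$geometry; fb <- config$fabrication; md <- config$modeling
  scale <- image_scale(g$microns_per_pixel, g$tile_size)
  params <- print_params(dilation_um = fb$dilation_um,
                         p_string = fb$p_string,
                         string_thickness_um = fb$string_thickness_um,
                         p_defect = fb$p_defect,
                         roughness_sigma_um = fb$roughness_sigma_um,
                         seed = fb$seed)
  keep <- keep_tiles || isTRUE(md$run_anomaly) || isTRUE(md$run_classifiers)
  tiles <- list(); tile_labels <- character(0); tile_groups <- character(0)
  metric_rows <- vector("list", nrow(conditions))
  k <- 0L
  per_cond <- function(rec) {
    k <<- k + 1L
    pair <- align_masks(rec$etched, rec$cad,
                        method = config$pipeline$align_method)
    pc <- compare_pixels(pair)
    sm <- compute_similarity(pc)
    metric_rows[[k]] <<- cbind(rec$condition,
                               data.frame(TP = pc$TP, TN = pc$TN,
                                          FP = pc$FP, FN = pc$FN),
                               as.data.frame(unclass(sm)[1:5]))
    if (keep) {
      tl <- split_array(rec$etched, n_needles = g$n_needles, scale = scale)
      tiles <<- c(tiles, tl)
      tile_labels <<- c(tile_labels, rec$ground_truth$label)
      tile_groups <<- c(tile_groups,
                        rep(rec$condition$condition_id, length(tl)))
    }
    NULL
  }
  generate_dataset(conditions, params = params, scale = scale,
                   n_needles = g$n_needles, pitch_um = g$pitch_um,
                   base_strip_um = g$base_strip_um,
                   etch_rate_um_per_mh = fb$etch_rate_um_per_mh,
                   per_condition = per_cond)
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL

  labels <- binarize_quality(metrics,
                             quality_labeler("sensitivity",
                                             md$quality_threshold))
  tree <- NULL; tree_eval <- NULL
  if (length(unique(labels)) == 2) {
    tree <- optimize_tree(metrics[quality_features], labels,
                          folds = md$folds, seed = md$seed)
    tree_eval <- evaluate_tree(tree, metrics[quality_features], labels,
                               folds = md$folds, seed = md$seed)
  }
  out <- list(config = config, metrics = metrics, labels = labels,
              tree = tree, tree_eval = tree_eval)
  if (keep) {
    out$tiles <- tiles
    out$tile_labels <- tile_labels
    out$tile_groups <- tile_groups
  }
  if (isTRUE(md$run_classifiers)) {
    proj <- fit_pixel_pca(tiles, n_components = md$n_components)
    feats <- flatten_and_project(tiles, proj)
    out$classifier_table <- run_classifier_suite(
      feats, tile_labels,
      split = split_config(n_repeats = md$n_repeats, seed = md$seed),
      groups = tile_groups)
  }
  if (isTRUE(md$run_anomaly)) {
    normal <- which(tile_labels == "non-defective")
    ntrain <- min(md$anomaly_train_count, length(normal) - 1)
    tr <- with_seed(md$seed, sample(normal, ntrain))
    model <- fit_padim(tiles[tr], padim_config(seed = md$seed))
    te <- setdiff(seq_along(tiles), tr)
    sc <- score_anomaly_batch(tiles[te], model)
    out$anomaly <- list(
      train_count = ntrain,
      scores = data.frame(tile = te, image_score = sc$image_scores,
                          label = tile_labels[te]),
      auc = evaluate_auc(sc$image_scores, tile_labels[te] == "defective"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    if (!is.null(tree)) {
      tree_to_json(tree, file.path(out_dir, "model.json"))
      utils::write.csv(as.data.frame(tree_eval$confusion),
                       file.path(out_dir, "confusion.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$classifier_table)) {
      utils::write.csv(out$classifier_table,
                       file.path(out_dir, "classifiers.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$anomaly)) {
      utils::write.csv(out$anomaly$scores,
                       file.path(out_dir, "anomaly_scores.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Render a Markdown report for a completed run
#'
#' Summarizes a [run_pipeline()] result (or a run directory holding its CSV
#' artifacts) into a human-readable Markdown report: similarity-metric
#' summary, quality-class balance, tree hyperparameters and confusion
#' matrix, and any optional-stage tables. Regeneration is idempotent.
#'
#' @param run a `run_pipeline()` result list or a run directory path.
#' @param path output `.md` file; defaults to `report.md` inside the run
#'   directory when `run` is a path.
#' @return the path, invisibly.
#' @export
render_report <- function(run, path = NULL) {
  if (is.character(run)) {
    dirp <- run
    mfile <- file.path(dirp, "metrics.csv")
    if (!file.exists(mfile)) {
      stop("incomplete run: missing artifact metrics.csv in ", dirp)
    }
    metrics <- utils::read.csv(mfile)
    if (is.null(path)) path <- file.path(dirp, "report.md")
    run <- list(metrics = metrics)
  }
  if (is.null(path)) stop("`path` is required when reporting from a list")
  m <- run$metrics
  lines <- c("# Microneedle array quality-control report", "",
             sprintf("Conditions processed: %d", nrow(m)), "",
             "## Similarity metrics (mean over conditions)", "")
  metric_cols <- c("similarity_index", "area_ratio", "accuracy",
                   "sensitivity", "dice")
  lines <- c(lines, "| metric | mean | min | max |", "|---|---|---|---|")
  for (mc in metric_cols) {
    lines <- c(lines, sprintf("| %s | %.4f | %.4f | %.4f |",
                              mc, mean(m[[mc]]), min(m[[mc]]), max(m[[mc]])))
  }
  if (!is.null(run$labels)) {
    lines <- c(lines, "",
               sprintf("Quality classes at the 0.8 sensitivity threshold: %d high / %d low",
                       sum(run$labels == 1), sum(run$labels == 0)))
  }
  if (!is.null(run$tree)) {
    ev <- run$tree_eval
    lines <- c(lines, "", "## Quality classification tree", "",
               sprintf("Optimal criterion: %s; maximum splits: %d",
                       run$tree$criterion, run$tree$max_splits), "",
               "Pooled cross-validated confusion matrix (rows = true):", "",
               "| | pred 0 | pred 1 |", "|---|---|---|",
               sprintf("| true 0 | %d | %d |", ev$confusion[1, 1],
                       ev$confusion[1, 2]),
               sprintf("| true 1 | %d | %d |", ev$confusion[2, 1],
                       ev$confusion[2, 2]), "",
               sprintf("Accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%",
                       ev$report$accuracy_pct, ev$report$sensitivity_pct,
                       ev$report$specificity_pct))
  }
  if (!is.null(run$classifier_table)) {
    ct <- run$classifier_table
    lines <- c(lines, "", "## Tile classifier suite", "",
               "| model | precision | recall | F1 | accuracy |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(ct))) {
      lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.3f | %.3f |",
                                ct$model[i], ct$precision[i], ct$recall[i],
                                ct$f1[i], ct$accuracy[i]))
    }
  }
  if (!is.null(run$anomaly)) {
    lines <- c(lines, "", "## Anomaly detection", "",
               sprintf("Training tiles: %d; image-level ROC-AUC: %.3f",
                       run$anomaly$train_count, run$anomaly$auc))
  }
  writeLines(lines, path)
  invisible(path)
}
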