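#!/usr/bin/env Rscript

# Stage 5: the quality predictor.
#
# Regresses each similarity metric on the five fabrication features with
# 5-fold CV, binarizes sensitivity at 0.8 into high/low quality, optimizes
# the classification tree (max splits x split criterion), reports its
# pooled-CV confusion matrix, serializes the tree to portable JSON, and
# demonstrates range-validated predictions. Requires the stage-2 cache.

suppressPackageStartupMessages(library(mnaqc))

cache <- "scratch/factorial_cache.rds"
if (!file.exists(cache)) stop("run analysis/02_similarity_metrics.R first")
d <- readRDS(cache)
seed <- 1L
metrics <- d$metrics

reg <- fit_metric_regressions(metrics, seed = seed)
r2 <- do.call(rbind, lapply(names(reg), function(m) {
  data.frame(metric = m, best_family = reg[[m]]$best,
             mean_r2 = round(reg[[m]]$best_r2, 3))
}))
write.csv(r2, "results/regression_r2.csv", row.names = FALSE)
cat("best regression family per similarity metric:\n")
print(r2)

labels <- binarize_quality(metrics)
cat("\nquality classes at the 0.8 sensitivity threshold:",
    sum(labels == 1), "high /", sum(labels == 0), "low\n")

feats <- metrics[c("base_diameter_um", "height_um", "draft_angle_deg",
                   "concentration_m", "duration_h")]
tree <- optimize_tree(feats, labels, seed = seed)
print(tree)
ev <- evaluate_tree(tree, feats, labels, seed = seed)
cat("pooled-CV confusion matrix (rows = true class):\n")
print(ev$confusion)
cat(sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
            ev$report$accuracy_pct, ev$report$sensitivity_pct,
            ev$report$specificity_pct))

tree_to_json(tree, "results/quality_tree.json")

example <- c(base_diameter_um = 1500, height_um = 2000, draft_angle_deg = 5,
             concentration_m = 5, duration_h = 14)
cat("\nexample prediction (1500 um base, 2000 um height, 5 deg, 5 M, 14 h):",
    predict_quality(example, tree), "\n")
bad <- example; bad["concentration_m"] <- 25
cat("out-of-range request is rejected:",
    tryCatch(predict_quality(bad, tree), error = conditionMessage), "\n")

run <- list(metrics = metrics, labels = labels, tree = tree, tree_eval = ev)
render_report(run, "results/report.md")
cat("wrote results/regression_r2.csv, results/quality_tree.json, results/report.md\n")
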