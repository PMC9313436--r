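#!/usr/bin/env Rscript

# Stage 4: backbone-free patch-distribution anomaly detection.
#
# Fits per-position multivariate Gaussians on 450 defect-free tiles, scores
# every remaining tile by maximum Mahalanobis distance, reports the
# image-level ROC-AUC, and exports a handful of 0-255 anomaly heat maps.
# Requires the stage-2 cache.

suppressPackageStartupMessages(library(mnaqc))

cache <- "scratch/factorial_cache.rds"
if (!file.exists(cache)) stop("run analysis/02_similarity_metrics.R first")
d <- readRDS(cache)
seed <- 1L

normal <- which(d$labels == "non-defective")
cat("defect-free tiles available:", length(normal), "\n")
tr <- mnaqc:::with_seed(seed, sample(normal, min(450, length(normal) - 1)))
model <- fit_padim(d$tiles[tr], padim_config(seed = seed))
te <- setdiff(seq_along(d$tiles), tr)
sc <- score_anomaly_batch(d$tiles[te], model)
auc <- evaluate_auc(sc$image_scores, d$labels[te] == "defective")
cat(sprintf("image-level ROC-AUC on %d test tiles: %.3f\n", length(te), auc))

scores <- data.frame(tile = te, image_score = sc$image_scores,
                     label = d$labels[te])
write.csv(scores, "results/anomaly_scores.csv", row.names = FALSE)

# export heat maps for the three strongest and three weakest anomalies
dir.create("results/anomaly_maps", showWarnings = FALSE)
ord <- order(sc$image_scores)
pick <- te[c(utils::head(ord, 3), utils::tail(ord, 3))]
maps <- lapply(pick, function(i) score_anomaly(d$tiles[[i]], model)$map)
maps8 <- rescale_anomaly_maps(maps)
for (k in seq_along(pick)) {
  png::writePNG(maps8[[k]] / 255,
                sprintf("results/anomaly_maps/tile_%04d_%s.png", pick[k],
                        d$labels[pick[k]]))
}
cat("wrote results/anomaly_scores.csv and results/anomaly_maps/\n")
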