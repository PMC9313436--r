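#!/usr/bin/env Rscript

# Stage 3: classical defect classification of single-needle tiles.
#
# Flattens the 150x150 tiles to 22,500-vectors, reduces them to 10
# principal components (fitted with the Gram-matrix trick), and runs the
# five-model classifier suite on repeated 75/10/15 splits grouped by source
# array. Requires the stage-2 cache.

suppressPackageStartupMessages(library(mnaqc))

cache <- "scratch/factorial_cache.rds"
if (!file.exists(cache)) stop("run analysis/02_similarity_metrics.R first")
d <- readRDS(cache)

proj <- fit_pixel_pca(d$tiles, n_components = 10)
cat("PCA: kept", ncol(proj$rotation), "of 22,500 pixel dimensions;",
    sprintf("%.1f%%", 100 * sum(proj$sdev^2) / proj$total_var),
    "of pixel variance explained\n")
feats <- flatten_and_project(d$tiles, proj)

tab <- run_classifier_suite(feats, d$labels,
                            split = split_config(n_repeats = 5, seed = 1),
                            groups = d$groups)
write.csv(tab, "results/classifier_table.csv", row.names = FALSE)
print(tab[c("model", "precision", "recall", "f1", "accuracy")])
cat("wrote results/classifier_table.csv\n")
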