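#!/usr/bin/env Rscript

# Stage 2: CAD-vs-fabricated pixel comparison.
#
# Runs the full pipeline over the factorial (render -> print -> etch ->
# align -> compare), writes the per-condition confusion counts and the five
# similarity metrics, and saves example four-color overlays for one design
# followed across all four concentrations. Tiles are cached in scratch/ for
# stages 3 and 4.

suppressPackageStartupMessages(library(mnaqc))

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

run <- run_pipeline(default_run_config(seed = seed), keep_tiles = TRUE)
write.csv(run$metrics, "results/metrics.csv", row.names = FALSE)
saveRDS(list(tiles = run$tiles, labels = run$tile_labels,
             groups = run$tile_groups, metrics = run$metrics,
             labels_quality = run$labels),
        "scratch/factorial_cache.rds")

cat("metric summary over", nrow(run$metrics), "conditions:\n")
print(round(sapply(run$metrics[c("similarity_index", "area_ratio",
                                 "accuracy", "sensitivity", "dice")],
                   summary), 4))

# overlays: design 8 across the four concentrations at 14 h
ex <- subset(condition_grid(), design_id == "d08" & duration_h == 14)
dir.create("results/overlays", showWarnings = FALSE)
invisible(generate_dataset(ex, print_params(seed = seed),
                           per_condition = function(rec) {
  pair <- align_masks(rec$etched, rec$cad)
  write_overlay_png(pair, file.path("results/overlays",
                                    paste0(rec$condition$condition_id,
                                           ".png")))
  NULL
}))
cat("wrote results/metrics.csv and results/overlays/\n")
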