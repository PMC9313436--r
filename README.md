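# mnaqc — quality assessment of 3D-printed microneedle arrays

Microneedle arrays (MNAs) for transdermal drug delivery can be fabricated
cheaply on desktop fused-deposition (FDM) printers and finished by etching in
KOH solution, which dissolves the stringing and over-extrusion artifacts the
nozzle leaves between needles — but too strong a dose erodes the needle
bodies themselves. `mnaqc` is an R implementation of an image-based quality
control pipeline for this process, aimed at fabrication researchers who want
to predict, from design and etching parameters alone, whether a print will
come out usable.

The pipeline works entirely on binary side-view silhouettes:

1. **CAD geometry** — render the ideal silhouette of a needle (symmetric
   trapezoid: base diameter *b*, height *h*, draft angle *θ* from the
   vertical, tip width `max(0, b − 2·h·tan θ)`) and of one-row 10-needle
   arrays.
2. **Synthetic fabrication** — simulate printing (inter-needle strings,
   boundary roughness, tip truncation) and etching (morphological erosion by
   a disc of radius `d = k·C·t`, with concentration *C* in M, duration *t*
   in h, and `k = 0.2667 µm/(M·h)` calibrated so a 1000 µm base etched at
   5 M × 18 h comes out at ~952 µm), with per-needle defect ground truth.
3. **Image pipeline** — binarize (Otsu), split arrays into 150×150
   single-needle tiles, align fabricated to CAD silhouettes
   (integer-pixel translation), and count per-pixel agreement into
   TP/TN/FP/FN (a pixel is *positive* when it is needle material, *true*
   when both masks agree).
4. **Similarity metrics** — from each confusion:
   similarity index `(TP−FP)/(TP+FN)`, area ratio `(TP+FP)/(TP+FN)`,
   accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, and intersection-
   over-union `TP/(TP+FP+FN)`.
5. **Defect detection** — classical classifiers (SGD-style linear, tree,
   naïve Bayes, MLP, SVM) on 10 principal components of the flattened
   tiles, and backbone-free patch-distribution anomaly detection
   (per-position multivariate Gaussians over handcrafted patch embeddings,
   scored by Mahalanobis distance, evaluated by image-level ROC-AUC).
6. **Quality prediction** — per-metric regression (linear, tree, SVM,
   squared-exponential Gaussian process, neural net) with 5-fold CV mean
   R², sensitivity binarized at 0.8 into high/low quality, and a
   classification tree whose hyperparameters (maximum splits 1–50, Gini vs
   cross-entropy) are grid-searched by cross-validated accuracy.

## Worked example

```r
library(mnaqc)

# one fabricated condition: design 4, mild etch
arr <- render_array(mn_design(1000, 2500, 5))         # CAD silhouette
pr  <- simulate_print(arr, print_params(seed = 1))    # printed + ground truth
et  <- simulate_etch(pr$mask, etching_dose(5, 18))    # etched
mean(measure_needles(et)$base_um)
#> [1] 952.5        # designed 1000 um, measured ~952 um in the lab

pair <- align_masks(et, arr)
compute_similarity(compare_pixels(pair))
#> similarity_index 0.854, area_ratio 0.857, accuracy 0.963,
#> sensitivity 0.856, dice 0.854
```

The numbered scripts under `analysis/` run the full study on the synthetic
factorial (10 designs × 4 concentrations × 6 durations = 240 arrays, 2400
needles) and write tables under `results/`. On the default seed they print,
among other things:

```
defect rate by erosion depth bucket:
   (0,45]  (45,100] (100,150]
    0.870     0.620     0.558      # etching removes imperfections

image-level ROC-AUC on 1950 test tiles: 0.996   # anomaly detection

quality classes at the 0.8 sensitivity threshold: 219 high / 21 low
pooled-CV confusion matrix (rows = true class):
    predicted
true  0   1
   0 13   8
   1  1 218
accuracy 96.25%, sensitivity 99.54%, specificity 61.90%
```

`predict_quality()` serves the final tree with validated input ranges
(e.g. concentration must lie in [3, 21.6] M):

```r
predict_quality(c(base_diameter_um = 1500, height_um = 2000,
                  draft_angle_deg = 5, concentration_m = 5,
                  duration_h = 14), tree)
#> [1] "High"
```

## Package layout

* `R/` — the implementation (geometry, fabrication simulator, image
  pipeline, metrics, classifiers, anomaly detection, quality model,
  orchestration).
* `analysis/01…05_*.R` — the study workflow as thin narrative drivers.
* `vignettes/microneedle-qc.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests backed
  by brute-force oracles.
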