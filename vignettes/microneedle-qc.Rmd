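---
title: "Methods: image-based quality control of 3D-printed microneedle arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based quality control of 3D-printed microneedle arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mnaqc)
```

# The problem

Fused-deposition (FDM) printing is the cheapest route to polymer microneedle
arrays, but at sub-millimeter feature sizes the nozzle leaves material traces
("strings") between needles, the extrusion boundary is rough, and tips
occasionally fail to form. Etching the printed PLA part in KOH solution
dissolves surface material and removes these imperfections; overdone, it
also removes needle bodies, and tall, slender needles become brittle. The
quality of a fabricated array is therefore a trade-off governed by five
parameters: three geometric (needle base diameter, height, draft angle) and
two chemical (KOH concentration, etch duration).

`mnaqc` quantifies that trade-off on binary side-view silhouettes. Because
the original study's photographs are not public, the package includes a
first-class synthetic generator that emulates the fabrication process; every
downstream stage — pixel comparison, similarity metrics, defect
classification, anomaly detection, and the quality predictor — runs
identically on synthetic masks and on binarized photographs supplied by the
user.

# Silhouette geometry

A needle design is rendered as a symmetric trapezoid standing on a base
strip: half-width at height $y$ above the base is
$b/2 - y\tan\theta$, clamped at zero (a pure cone when the taper closes
early; a rectangle at $\theta = 0$). Pixels are foreground when their center
falls inside the shape; with the default scale of 25 µm/px a 150-pixel tile
spans 3750 µm, enough for the tallest (3000 µm) design plus a 250 µm base
strip. Arrays place ten identical profiles at a 2500 µm center-to-center
pitch. The pitch and strip thickness are not reported by the study and were
chosen once so that the widest (1500 µm) needles keep a 1000 µm clearance;
both are configurable. Rendering is deterministic and mirror-symmetric up to
one pixel column.

# The fabrication simulator

`simulate_print()` applies, in order:

* **over-extrusion** — uniform dilation by `dilation_um`. The default is 0:
  a flank dilation below half a pixel (12.5 µm) cannot be represented at
  the working scale, and the measured reference case (below) implies the
  printed base is close to nominal. The knob exists for coarser emulations.
* **stringing** — for each gap between adjacent needles, with probability
  `p_string` (default 0.7) a horizontal band of thickness
  `string_thickness_um` (default 40 µm) bridges the two flanks at a random
  height in the lower 15–60 % of the needle. 40 µm keeps the band one to
  two pixel rows thick, so the mild doses that practitioners report as
  "cleaning" a print do remove it before needle flanks erode materially.
* **boundary roughness** — every boundary pixel flips with the probability
  that a $N(0, \sigma)$ normal displacement exceeds half a pixel
  (`roughness_sigma_um = 10` µm by default, giving a flip probability of
  about 0.21).
* **tip truncation** — with probability `p_defect` (default 0.15) a needle
  loses a uniform 30–60 % of its height.

All draws come from a substream keyed by the *design*, not the full
condition: the same printed realization is etched at every dose of that
design, mirroring how one physical print is followed across etching
conditions, and making the dose–response of pixel errors strictly monotone
at fixed seed. Reruns are bit-identical.

`simulate_etch()` erodes the printed mask by a disc of radius
$d = k \, C \, t$ µm. The linear rate law is the simplest model consistent
with alkaline hydrolysis being surface-limited; the study reports no rate
law, but it reports one calibration datum: a 1000 µm base (design 4,
1000 × 2500 µm, 5°) etched at 5 M for 18 h measured ~952 µm, i.e. ~24 µm
lost per side. With $C t = 90$ M·h this fixes $k = 24/90 = 0.2667$
µm/(M·h), the package default. Erosion is implemented on the Euclidean
distance transform, so masks at increasing doses are exactly nested — the
etch can only remove material, never move it. At 25 µm/px the radius rounds
to whole pixels, so doses within ~94 M·h·$k$ of each other can alias to the
same erosion; this is documented, desk-scale behavior. At strong doses
(erosion depth ≥ 30 µm) needles of designs at least 2750 µm tall
additionally break with probability 0.6, losing 20–50 % of their height —
the high-aspect brittleness observed experimentally.

**Ground truth.** A needle is labelled defective when its tip was truncated,
it broke during etching, or visible string material (at least 4 px ≈ one
100 µm stub) still touches it after etching. Labels are assigned on the
*etched* product because that is what an expert reviews; the print-stage
label is kept in a separate column. On the defaults the factorial yields
roughly 70 % defective tiles, concentrated at mild doses — the defect rate
falls from 0.87 below 45 M·h to 0.56 above 100 M·h, reproducing the
"etching removes imperfections" narrative.

# Image pipeline

*Binarization* uses Otsu's threshold on a 256-level histogram (constant
images are rejected rather than guessed). *Tiling* locates needle centers as
runs of the vertical-projection profile above the base strip — strings add
only a thin floor to the profile, so stringing cannot merge detections the
way connected-component labelling would — cuts at midpoints between
centers, and pads each cut into a 150 × 150 tile with the needle centered.
The cut windows partition the needle region exactly: no foreground pixel is
lost or duplicated.

*Alignment* is translation-only with integer shifts, which keeps masks
strictly binary; CAD and photo pairs share orientation, so rotation/scale
registration is out of scope. The obvious estimator — match the bottom
foreground row and the horizontal centroid — turned out to be unstable by
design: when a dose removes strings or an outer needle breaks, the centroid
moves by a rounding step and the recovered shift jitters by ±1 px between
doses, which breaks the monotone dose–response of FP/FN. The default
therefore initializes from the 1-D projection-profile cross-correlation and
refines by maximizing pixel overlap over a local window, ties broken toward
the smaller shift; the centroid variant remains available
(`align_masks(..., method = "centroid")`).

*Comparison* counts TP (material in both), TN (background in both), FP
(material only in the fabricated mask), FN (material only in CAD); the four
counts always sum to the canvas area.

# Similarity metrics

From each confusion the five study metrics are computed at full precision:
similarity index $1 - (FP+FN)/(TP+FN) \equiv (TP-FP)/(TP+FN)$ (not clipped;
negative when FP exceeds TP), area ratio $(TP+FP)/(TP+FN)$ (unbounded
above), accuracy, sensitivity $TP/(TP+FN)$, and the "Dice similarity
coefficient" *as the study prints it*, $TP/(TP+FP+FN)$ — formally the
Jaccard index. Fidelity to the printed formula wins; the conventional Dice
$2TP/(2TP+FP+FN)$ is returned alongside as `dice_conventional`. Reported
percentages round half away from zero to two decimals, matching how such
tables are conventionally printed; raw ratios are never rounded.

# Defect classification

Tiles are flattened to 22,500-vectors and reduced to 10 principal
components. Since the tile count is far below the pixel count, the PCA is
fitted by eigendecomposition of the $n \times n$ Gram matrix; components
are orthonormal and identical (up to sign) to the covariance eigenvectors,
which the tests verify against the direct eigendecomposition on toys. The
projection is fitted on the training split only.

The classifier suite (logistic-linear, decision tree, Gaussian naïve Bayes,
MLP with one hidden layer of 100 units, RBF-kernel SVM) trains on
stratified 75/10/15 train/validation/test splits, uses the validation split
to pick within each family's small hyperparameter grid, and averages test
scores over 5 repeats. Splits are grouped by source array so the ten
sibling needles of one print can never straddle a split — the study does
not say whether it did this, but without grouping the near-identical
siblings leak across splits and inflate every score. Precision, recall and
F1 are macro-averaged over the two classes (the study reports single values
per model without stating its averaging).

# Anomaly detection

Patch-distribution modelling fits one multivariate Gaussian per patch-grid
position over embeddings of defect-free tiles and scores new tiles by
per-position Mahalanobis distance
$\sqrt{(x-\mu)^\top(\Sigma + \varepsilon I)^{-1}(x-\mu)}$; there is no
iterative training. The original method embeds patches with a pretrained
CNN; here the embedding is handcrafted — each tile is resized to 64 × 64
and a 16 × 16 grid of 4 × 4 cells concatenates the raw, Gaussian-smoothed
and gradient-magnitude pixels of the cell (48 dimensions) — which keeps the
probabilistic core intact, runs on one CPU with no pretrained weights, and
is pluggable. Shrinkage is $\varepsilon = 0.01 \cdot
\mathrm{tr}(\Sigma)/d$; random dimension selection from the original
method is implemented but off by default at this embedding size. Anomaly
maps are upsampled, smoothed, and min–max rescaled to 0–255 jointly across
a dataset so intensities are comparable between tiles; the image-level
score is the maximum raw position distance, and image-level ROC-AUC is the
Wilcoxon rank estimator with ties counted one half.

With 450 defect-free training tiles from the default factorial, the
detector separates defective tiles at image-level AUC ≈ 0.99. The published
figure on real photographs (0.919, with a pretrained backbone) is not
reproducible without those photographs; the synthetic result is a property
check — the method, minus its CNN, still detects the defect classes this
simulator produces — not a value match. Synthetic defects are geometrically
crisp; real prints blur, reflect, and vary in illumination, so real-photo
AUC should be expected lower.

# Quality prediction

Each similarity metric is regressed on the ordered five-feature vector
(base diameter, height, draft angle, concentration, duration — no
dimensionality reduction) with 5-fold CV; fold $R^2 = 1 - SS_{res}/SS_{tot}$
about the fold's own mean, and the reported value is the *mean of the five
fold values*, never a pooled fit (a test pins this against a hand-computed
two-fold case). Families: linear, regression tree, RBF-SVM,
squared-exponential Gaussian process (fixed kernel scale $\sigma = 0.1$ on
standardized features — the median heuristic for five standardized
dimensions; the automatic estimator over-smooths the dose surface), and a
small neural net. Features are standardized with training-fold statistics.

Sensitivity is binarized at 0.8 — values *below* 0.8 are Class 0 (low
quality), so the boundary value itself is Class 1 — and a classification
tree is optimized by 5-fold CV accuracy over maximum splits 1–50 × split
criterion (Gini diversity vs cross-entropy), ties toward fewer splits and
then Gini. The split budget is enforced by growing a full tree at cp = 0
and pruning back along the complexity path to the largest subtree within
budget. The winner is refit on all data; `evaluate_tree()` reports the
pooled cross-validated confusion matrix by default (a hold-out variant
exists, since the study does not say which its printed table is).
`predict_quality()` validates each feature against closed ranges —
concentration hard-bounded to [3, 21.6] M on physical grounds, the others
plausibility defaults flagged as such in `input_ranges()` — and answers
"High" or "Low". The tree serializes to portable JSON
(`tree_to_json()` / `predict_tree_json()`), with round-tripped predictions
tested to be identical.

# Validation design

Two planted-truth generators drive the protocol-level tests. For the tree:
quality is a threshold rule on dose $C\,t$ whose cutoff depends on a coarse
height group (50 M·h below 2500 µm, 42 M·h at or above), with independent
5 % label flips as the default noise; every (group, dose) cell has several
replicates, so pooled-CV accuracy of an ideal learner is limited only by the
flips. The optimized tree reaches 1.00 noiseless and ≈ 0.95–0.98 at default
noise. For the regressions: smooth metric surfaces whose sensitivity rises
to an optimum at mild dose and falls beyond it, on which the
squared-exponential GP must beat the linear family, and permuted responses
must score near zero.

Problem sizes used throughout the tests and the acceptance script are the
study's own: the full 240-condition factorial with 2400 tiles, 450
anomaly-training tiles, 5-fold CV on 240 rows.

# Known limitations

* The simulator works at silhouette level only: no layer texture,
  illumination, perspective, or camera noise, and its etch model is
  isotropic with a single calibrated rate — real etching is heterogeneous
  ("patchy"), which the roughness term only caricatures. Passing tests
  demonstrate correctness of the pipeline and recoverability of planted
  truth, not photographic realism.
* Erosion radii quantize to 25 µm pixels, so nearby doses alias; use a
  finer `image_scale` when that matters.
* Published classifier/CNN scores and the PaDiM AUC on the study's
  photographs are not reproducible here (data and pretrained weights
  unavailable); they are replaced by the property checks described above.
* Absolute image scale (µm/px of the photographs) and the within-array
  needle spacing are free parameters; the defaults are stated, not derived.
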