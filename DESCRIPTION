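Package: mnaqc
Title: Quality Assessment of 3D-Printed Microneedle Arrays from Silhouette Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Image-based quality control for microneedle arrays fabricated by
    fused-deposition 3D printing and finished by alkaline (KOH) etching. The
    package renders ideal CAD side-view silhouettes from needle design
    parameters, simulates print artifacts (stringing, boundary roughness, tip
    truncation) and dose-dependent etch erosion to produce a fully labelled
    synthetic dataset, compares fabricated silhouettes to their CAD references
    pixel by pixel, and derives five similarity metrics from the resulting
    pixel confusion counts. On top of the metric table it fits per-metric
    regressions (linear, tree, SVM, Gaussian process, neural network) with
    5-fold cross-validation, binarizes the sensitivity metric at 0.8 into a
    high/low quality label, and optimizes a classification tree (maximum
    splits and split criterion) to predict fabrication quality from three
    geometric and two etching features. Defect detection on single-needle
    tiles is provided both as classical classifiers on PCA-reduced pixels and
    as backbone-free patch-distribution anomaly detection (per-position
    multivariate Gaussians scored by Mahalanobis distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    rpart,
    e1071,
    kernlab,
    nnet,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
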