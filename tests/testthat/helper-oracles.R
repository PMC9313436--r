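# Independent brute-force oracles used to validate the fast implementations.

# per-pixel double-loop confusion counting
oracle_confusion <- function(cad, printed) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(cad))) {
    for (j in seq_len(ncol(cad))) {
      c_ <- cad[i, j]; p_ <- printed[i, j]
      if (p_ == 1 && c_ == 1) tp <- tp + 1L
      else if (p_ == 0 && c_ == 0) tn <- tn + 1L
      else if (p_ == 1 && c_ == 0) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# AUC by exhaustive pair counting, ties as one half
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Otsu by exhaustive sweep over 256 candidate thresholds, maximizing
# between-class variance
oracle_otsu <- function(img01) {
  v <- as.numeric(img01)
  best_t <- NA; best_var <- -1
  for (t in (0:255) / 255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

random_confusion <- function() {
  pixel_confusion(tp = sample(1:500, 1), tn = sample(0:500, 1),
                  fp = sample(0:500, 1), fn = sample(0:500, 1))
}

random_small_mask <- function(nr = 8, nc = 8, p = 0.4) {
  binary_mask(matrix(as.integer(runif(nr * nc) < p), nr, nc))
}

# a clean (artifact-free) rendered test array, small enough for fast tests
clean_test_array <- function(n_needles = 10, design = mn_design(1000, 2000, 5)) {
  render_array(design, n_needles = n_needles)
}

no_artifact_params <- function(seed = 1) {
  print_params(dilation_um = 0, p_string = 0, string_thickness_um = 0,
               p_defect = 0, roughness_sigma_um = 0, seed = seed)
}
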