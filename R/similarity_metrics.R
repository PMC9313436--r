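#' Similarity metrics from a pixel confusion
#'
#' The five metrics used to summarize agreement between a fabricated
#' silhouette and its CAD reference:
#'
#' * `similarity_index` = 1 - (FP+FN)/(TP+FN), the complement of the false
#'   pixel fraction relative to the CAD needle area; algebraically equal to
#'   (TP-FP)/(TP+FN). Not clipped: it goes negative when FP exceeds TP.
#' * `area_ratio` = (TP+FP)/(TP+FN), fabricated-to-designed foreground area;
#'   has no upper bound and exceeds 1 under over-printing.
#' * `accuracy` = (TP+TN)/total.
#' * `sensitivity` = TP/(TP+FN), the fraction of designed needle area that
#'   was actually fabricated.
#' * `dice` = TP/(TP+FP+FN), intersection over union. (This is the "Dice
#'   similarity coefficient" as used in the source protocol; the
#'   conventional Dice 2TP/(2TP+FP+FN) is returned as `dice_conventional`.)
#'
#' @param pc a [pixel_confusion()].
#' @return a list of class `similarity_metrics`.
#' @examples
#' compute_similarity(pixel_confusion(tp = 2, tn = 5, fp = 1, fn = 1))
#' @export
compute_similarity <- function(pc) {
  tp <- pc$TP; tn <- pc$TN; fp <- pc$FP; fn <- pc$FN
  if (tp + fn == 0) stop("empty CAD foreground: similarity metrics undefined")
  total <- tp + tn + fp + fn
  structure(list(
    similarity_index = 1 - (fp + fn) / (tp + fn),
    area_ratio = (tp + fp) / (tp + fn),
    accuracy = (tp + tn) / total,
    sensitivity = tp / (tp + fn),
    dice = tp / (tp + fp + fn),
    dice_conventional = 2 * tp / (2 * tp + fp + fn)
  ), class = "similarity_metrics")
}

#' 2x2 classification statistics
#'
#' Standard derived statistics of a binary confusion table. Metrics with a
#' zero denominator are reported as `NA` (undefined), never as 0.
#'
#' @param tp,tn,fp,fn counts of true/false positives/negatives.
#' @return a list of class `classification_report` with `precision`,
#'   `recall` (= sensitivity), `specificity`, `f1`, `accuracy`, plus
#'   two-decimal half-up-rounded percentage versions (`accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct`) matching how such tables are
#'   conventionally printed.
#' @examples
#' r <- compute_classification_report(tp = 128, tn = 98, fp = 7, fn = 7)
#' r$accuracy_pct     # 94.17
#' r$sensitivity_pct  # 94.81
#' r$specificity_pct  # 93.33
#' @export
compute_classification_report <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (identical(tp, 0L) || tp == 0) 0 else NA_real_
  specificity <- div(tn, tn + fp)
  accuracy <- (tp + tn) / total
  structure(list(
    precision = precision, recall = recall, specificity = specificity,
    f1 = f1, accuracy = accuracy,
    accuracy_pct = round_half_up(100 * accuracy, 2),
    sensitivity_pct = round_half_up(100 * recall, 2),
    specificity_pct = round_half_up(100 * specificity, 2),
    misclassified = fp + fn
  ), class = "classification_report")
}

#' Round half away from zero
#'
#' Fixed-precision rounding where exact halves round up in magnitude
#' (`94.165 -> 94.17`), matching how percentages are conventionally printed,
#' unlike R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
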