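# Confusion-matrix metrics, segmentation overlap measures, and the
# stratified k-fold harness (with the pseudo-modality leakage rule: synthetic
# scans may appear in training splits only).

#' Confusion counts for a binary task
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive The positive-class label.
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  p <- predicted == positive
  t <- truth == positive
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t),
       FN = sum(!p & t))
}

#' Classification metrics from confusion counts
#'
#' Metrics with zero denominators are reported as `NA` (explicitly
#' undefined), never silently 0.
#'
#' @param c List with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @return Named list: accuracy, precision, sensitivity, specificity, f1,
#'   npv, mcc, fpr, fnr (all fractions).
#' @export
#' @examples
#' classification_metrics(list(TP = 90, FP = 10, TN = 85, FN = 15))$accuracy
classification_metrics <- function(c) {
  with(c, {
    total <- TP + FP + TN + FN
    if (total < 1) stop("empty confusion table")
    sdiv <- function(num, den) if (den > 0) num / den else NA_real_
    precision <- sdiv(TP, TP + FP)
    sensitivity <- sdiv(TP, TP + FN)
    specificity <- sdiv(TN, TN + FP)
    f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
              precision + sensitivity > 0)
      2 * precision * sensitivity / (precision + sensitivity) else NA_real_
    mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    list(accuracy = (TP + TN) / total,
         precision = precision,
         sensitivity = sensitivity,
         specificity = specificity,
         f1 = f1,
         npv = sdiv(TN, TN + FN),
         mcc = if (mcc_den > 0)
           max(-1, min(1, (TP * TN - FP * FN) / mcc_den)) else NA_real_,
         fpr = if (!is.na(specificity)) 1 - specificity else NA_real_,
         fnr = if (!is.na(sensitivity)) 1 - sensitivity else NA_real_)
  })
}

#' Dice coefficient and intersection-over-union of two masks
#'
#' Two empty masks score (1, 1) by convention (perfect agreement on
#' absence).
#'
#' @param a,b Same-shape binary masks.
#' @return List with `dice`, `iou`; `dice = 2 iou / (1 + iou)`.
#' @export
dice_iou <- function(a, b) {
  if (length(a) != length(b)) stop("shape mismatch")
  a <- as.logical(a); b <- as.logical(b)
  inter <- sum(a & b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(list(dice = 1, iou = 1))
  uni <- sum(a | b)
  list(dice = 2 * inter / (sa + sb), iou = inter / uni)
}

#' Stratified k-fold assignment with the pseudo-modality leakage rule
#'
#' Real (CT) samples are split into `k` folds with per-fold class
#' proportions within one sample of the global proportions; pseudo-modality
#' samples are never assigned to a validation/test fold (`fold = 0`,
#' training-only), mirroring the protocol that restricts evaluation to real
#' scans.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @param modality Optional modality vector (`"ct"` / `"pseudo-mri"`);
#'   `NULL` treats everything as real.
#' @return Integer vector of fold ids (1..k; 0 = training-only pseudo
#'   sample).
#' @export
stratified_kfold <- function(labels, k, seed = 1L, modality = NULL) {
  n <- length(labels)
  real <- if (is.null(modality)) rep(TRUE, n) else modality == "ct"
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels[real])) {
      idx <- which(real & labels == cl)
      if (length(idx) < k)
        stop("class '", cl, "' has fewer than k = ", k, " real samples")
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Percentile bootstrap confidence interval for a metric
#'
#' @param values Per-sample indicator or score vector.
#' @param stat Function applied to a resample (default mean).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Seed.
#' @return List: `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(values, stat = mean, n_boot = 1000, conf = 0.95,
                         seed = 1L) {
  est <- stat(values)
  bs <- with_seed(seed, replicate(n_boot, stat(sample(values, replace = TRUE))))
  q <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2])
}
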