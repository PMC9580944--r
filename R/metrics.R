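#' Matthews correlation coefficient from confusion counts
#'
#' Standard closed form; returns 0 whenever any factor of the denominator is
#' zero (degenerate confusion matrix).
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @export
mcc <- function(tp, fp, tn, fn) {
  if (min(tp, fp, tn, fn) < 0) stop("counts must be non-negative")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# accuracy, F1, BCE loss and MCC from probabilities + binary truth
binary_metrics <- function(p, y, threshold = 0.5) {
  stopifnot(length(p) == length(y))
  hard <- as.numeric(p > threshold)
  tp <- sum(hard == 1 & y == 1); fp <- sum(hard == 1 & y == 0)
  tn <- sum(hard == 0 & y == 0); fn <- sum(hard == 0 & y == 1)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  data.frame(
    accuracy = (tp + tn) / length(y),
    balanced_accuracy = mean(c(if (tp + fn > 0) rec else NA,
                               if (tn + fp > 0) tn / (tn + fp) else NA),
                             na.rm = TRUE),
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    loss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
    mcc = mcc(tp, fp, tn, fn))
}

#' Evaluate predictions against ground truth
#'
#' Granularities: `"per-base"` compares per-position pairedness labels;
#' `"per-entry"` compares base-pair matrices element-wise on the upper
#' triangle, binarized at 0.5; `"per-pair"` applies [matrix_to_structure()]
#' to the prediction and compares the resulting pair set against the true
#' pairs (precision/recall/F1/MCC over upper-triangle entries).
#'
#' @param pred predictions: list of probability vectors (per-base), list of
#'   matrices (per-entry / per-pair).
#' @param truth ground truth: list of 0/1 vectors, or list of `pair_table`s.
#' @param granularity `"per-base"`, `"per-entry"` or `"per-pair"`.
#' @return one-row data.frame: accuracy, balanced accuracy, F1, loss, MCC,
#'   plus the granularity tag.
#' @export
evaluate_predictions <- function(pred, truth,
                                 granularity = c("per-base", "per-entry",
                                                 "per-pair")) {
  granularity <- match.arg(granularity)
  if (length(pred) != length(truth)) stop("pred and truth must be aligned")
  ps <- numeric(0L); ys <- numeric(0L)
  for (k in seq_along(pred)) {
    if (granularity == "per-base") {
      y <- if (inherits(truth[[k]], "pair_table"))
        as.numeric(!is.na(truth[[k]]$partner)) else as.numeric(truth[[k]])
      p <- pred[[k]]
      if (length(p) != length(y)) stop("shape mismatch at element ", k)
      ps <- c(ps, p); ys <- c(ys, y)
    } else {
      tm <- if (inherits(truth[[k]], "pair_table")) structure_matrix(truth[[k]])
            else truth[[k]]
      pm <- pred[[k]]
      if (!all(dim(pm) == dim(tm))) stop("shape mismatch at element ", k)
      if (granularity == "per-pair")
        pm <- structure_matrix(matrix_to_structure(pm))
      ut <- upper.tri(tm)
      ps <- c(ps, pm[ut]); ys <- c(ys, tm[ut])
    }
  }
  cbind(binary_metrics(ps, ys), granularity = granularity)
}
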