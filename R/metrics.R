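#' Segmentation overlap metrics
#'
#' Pixel-set metrics between a predicted and a reference binary mask: Jaccard
#' (JSC) and Dice (DSC) similarity coefficients, accuracy, sensitivity,
#' precision and specificity, all from the true/false positive/negative pixel
#' counts. Two empty masks are defined as a perfect match (all metrics 1,
#' flagged via `empty_pair`); metrics with an undefined denominator are `NaN`.
#'
#' @param pred Predicted binary mask (`liver_mask` or 0/1 matrix).
#' @param truth Reference binary mask of the same shape.
#' @return Object of class `seg_metrics`: `jsc`, `dsc`, `acc`, `sen`, `pre`,
#'   `spe`, `empty_pair`.
#' @export
seg_metrics <- function(pred, truth) {
  a <- if (inherits(pred, "liver_mask")) pred$pixels else as.matrix(pred)
  b <- if (inherits(truth, "liver_mask")) truth$pixels else as.matrix(truth)
  if (!all(dim(a) == dim(b))) stop("masks must have equal shape")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary")
  tp <- sum(a == 1 & b == 1); tn <- sum(a == 0 & b == 0)
  fp <- sum(a == 1 & b == 0); fn <- sum(a == 0 & b == 1)
  empty <- (tp + fp + fn) == 0
  div <- function(num, den) if (den == 0) NaN else num / den
  out <- if (empty) {
    list(jsc = 1, dsc = 1, acc = 1, sen = 1, pre = 1, spe = 1)
  } else {
    list(jsc = tp / (tp + fp + fn),
         dsc = 2 * tp / (2 * tp + fp + fn),
         acc = (tp + tn) / (tp + tn + fp + fn),
         sen = div(tp, tp + fn),
         pre = div(tp, tp + fp),
         spe = div(tn, tn + fp))
  }
  structure(c(out, list(empty_pair = empty,
                        counts = c(tp = tp, tn = tn, fp = fp, fn = fn))),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> JSC %.4f DSC %.4f ACC %.4f SEN %.4f PRE %.4f SPE %.4f%s\n",
              x$jsc, x$dsc, x$acc, x$sen, x$pre, x$spe,
              if (x$empty_pair) " (both masks empty)" else ""))
  invisible(x)
}

#' Aggregate segmentation metrics over a set of mask pairs
#'
#' `macro` averages the per-image metrics; `micro` pools the pixel counts of
#' all pairs first and computes the metrics once.
#'
#' @param preds,truths Lists of binary masks.
#' @param mode "macro" (default) or "micro".
#' @return Named numeric vector (jsc, dsc, acc, sen, pre, spe).
#' @export
seg_metrics_set <- function(preds, truths, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  ms <- Map(seg_metrics, preds, truths)
  keys <- c("jsc", "dsc", "acc", "sen", "pre", "spe")
  if (mode == "macro") {
    vapply(keys, function(k)
      mean(vapply(ms, function(m) m[[k]], numeric(1)), na.rm = TRUE),
      numeric(1))
  } else {
    cnt <- Reduce(`+`, lapply(ms, `[[`, "counts"))
    tp <- cnt["tp"]; tn <- cnt["tn"]; fp <- cnt["fp"]; fn <- cnt["fn"]
    unname_ok <- c(jsc = tp / (tp + fp + fn),
                   dsc = 2 * tp / (2 * tp + fp + fn),
                   acc = (tp + tn) / (tp + tn + fp + fn),
                   sen = tp / (tp + fn), pre = tp / (tp + fp),
                   spe = tn / (tn + fp))
    stats::setNames(as.numeric(unname_ok), keys)
  }
}

#' Classification metrics from whole-frame predictions
#'
#' Builds the confusion counts from the frame-level predicted classes and
#' computes accuracy, sensitivity and specificity. If one class is absent
#' from the truth, the corresponding metric is `NA` with a warning.
#'
#' @param predictions List of `frame_prediction` objects.
#' @return Object of class `clf_metrics`: `acc`, `sen`, `spe`, plus the
#'   confusion counts.
#' @export
clf_metrics <- function(predictions) {
  if (length(predictions) == 0) stop("no predictions")
  y <- vapply(predictions, `[[`, integer(1), "true_label")
  yhat <- vapply(predictions, `[[`, integer(1), "predicted_class")
  tp <- sum(yhat == 1 & y == 1); tn <- sum(yhat == 0 & y == 0)
  fp <- sum(yhat == 1 & y == 0); fn <- sum(yhat == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  sen <- if (tp + fn == 0) { warning("no positive frames: SEN undefined"); NA_real_ }
         else tp / (tp + fn)
  spe <- if (tn + fp == 0) { warning("no negative frames: SPE undefined"); NA_real_ }
         else tn / (tn + fp)
  structure(list(acc = acc, sen = sen, spe = spe,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "clf_metrics")
}

#' @export
print.clf_metrics <- function(x, ...) {
  cat(sprintf("<clf_metrics> ACC %.4f SEN %s SPE %s (tp %d tn %d fp %d fn %d)\n",
              x$acc, format(x$sen, digits = 4), format(x$spe, digits = 4),
              x$counts["tp"], x$counts["tn"], x$counts["fp"], x$counts["fn"]))
  invisible(x)
}

#' ROC curve and AUC from continuous frame scores
#'
#' Threshold sweep over the unique scores (ties grouped into one step),
#' yielding a monotone ROC polyline from (0,0) to (1,1); the AUC is its
#' trapezoidal area, which equals the Mann-Whitney probability that a random
#' positive outscores a random negative (ties counted 1/2).
#'
#' @param scores Numeric vector of frame scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return List with `auc` and `roc` (data frame of fpr, tpr, threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))          # tie groups of equal scores
  tp <- tapply(y == 1, grp, sum)
  fp <- tapply(y == 0, grp, sum)
  tpr <- c(0, cumsum(tp) / np)
  fpr <- c(0, cumsum(fp) / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  roc <- data.frame(fpr = fpr, tpr = tpr,
                    threshold = c(Inf, s[!duplicated(s)]))
  list(auc = as.numeric(auc), roc = roc)
}

#' Plot an ROC curve
#'
#' @param x Result of [roc_auc()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_roc <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
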