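#' Pixel-level confusion matrix
#'
#' Accumulates truth-by-prediction pixel counts; rows are the true class,
#' columns the predicted class.  Matrices from several slices can be added
#' with `+` (counts are additive), which is how dataset-level ("micro")
#' metrics are assembled.
#'
#' @param pred,truth integer class grids of equal dimensions, values in
#'   `[0, C)`.
#' @param C number of classes.
#' @return a `C x C` integer matrix of class `confusion_matrix`, dimnames
#'   `truth` x `pred`.
#' @export
confusion_matrix <- function(pred, truth, C = 3L) {
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must have identical dimensions", call. = FALSE)
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p >= C) || any(t < 0L | t >= C))
    stop(sprintf("class values must lie in [0, %d)", C), call. = FALSE)
  cm <- matrix(tabulate(t + C * p + 1L, nbins = C * C), C, C)
  dimnames(cm) <- list(truth = 0:(C - 1), pred = 0:(C - 1))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest counts for a class
#'
#' Reduces a confusion matrix to the binary counts for class `c`:
#' `TP = cm[c, c]`, `FP` = rest of column `c`, `FN` = rest of row `c`,
#' `TN` = everything else.
#'
#' @param cm a [confusion_matrix()].
#' @param class class index in `[0, C)`.
#' @return named numeric vector `c(TP, FP, FN, TN)`.
#' @export
binary_counts <- function(cm, class) {
  C <- nrow(cm)
  if (class < 0 || class >= C) stop("`class` out of range", call. = FALSE)
  i <- class + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# ratio with the absent-class convention: 0/0 -> 1 if the class appears in
# neither mask, else 0
safe_ratio <- function(num, den, absent) {
  if (den > 0) return(unname(num / den))
  if (absent) 1 else 0
}

#' Per-class segmentation metrics from a confusion matrix
#'
#' Computes, per class via one-vs-rest counts: Dice (2TP/(2TP+FP+FN)),
#' Jaccard (TP/(TP+FP+FN)), sensitivity (recall, TP/(TP+FN)), specificity
#' (TN/(TN+FP)), PPV (precision, TP/(TP+FP)) and NPV (TN/(TN+FN)).
#' Undefined 0/0 ratios are reported as 1 when the class is absent from both
#' truth and prediction, else 0.  Aggregates are unweighted means over the
#' foreground classes (all classes except 0).
#'
#' @param cm a [confusion_matrix()].
#' @return list with `per_class` (data frame, one row per class) and
#'   `aggregate` (named vector of foreground means).
#' @export
segmentation_metrics <- function(cm) {
  C <- nrow(cm)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  rows <- lapply(seq_len(C) - 1L, function(cl) {
    b <- binary_counts(cm, cl)
    absent <- (b["TP"] + b["FN"] == 0) && (b["TP"] + b["FP"] == 0)
    data.frame(
      class = cl,
      dice = safe_ratio(2 * b["TP"], 2 * b["TP"] + b["FP"] + b["FN"], absent),
      jaccard = safe_ratio(b["TP"], b["TP"] + b["FP"] + b["FN"], absent),
      sensitivity = safe_ratio(b["TP"], b["TP"] + b["FN"], absent),
      specificity = safe_ratio(b["TN"], b["TN"] + b["FP"], absent),
      ppv = safe_ratio(b["TP"], b["TP"] + b["FP"], absent),
      npv = safe_ratio(b["TN"], b["TN"] + b["FN"], absent),
      row.names = NULL)
  })
  per_class <- do.call(rbind, rows)
  fg <- per_class[per_class$class > 0, , drop = FALSE]
  aggregate <- colMeans(fg[, -1, drop = FALSE])
  list(per_class = per_class, aggregate = aggregate)
}

#' Dataset-level accuracy and IoU summaries
#'
#' From an accumulated confusion matrix: global accuracy (trace/total),
#' mean accuracy (mean per-class recall), mean IoU (mean per-class Jaccard)
#' and weighted IoU (per-class Jaccard weighted by the true-pixel share of
#' each class).  Per-class 0/0 cases follow the same absent-class convention
#' as [segmentation_metrics()].
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector `c(global_accuracy, mean_accuracy, mean_iou,
#'   weighted_iou)`.
#' @export
dataset_metrics <- function(cm) {
  C <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  recall <- iou <- share <- numeric(C)
  for (cl in seq_len(C) - 1L) {
    b <- binary_counts(cm, cl)
    absent <- (b["TP"] + b["FN"] == 0) && (b["TP"] + b["FP"] == 0)
    recall[cl + 1] <- safe_ratio(b["TP"], b["TP"] + b["FN"], absent)
    iou[cl + 1] <- safe_ratio(b["TP"], b["TP"] + b["FP"] + b["FN"], absent)
    share[cl + 1] <- (b["TP"] + b["FN"]) / total
  }
  c(global_accuracy = sum(diag(cm)) / total,
    mean_accuracy = mean(recall),
    mean_iou = mean(iou),
    weighted_iou = sum(share * iou))
}

# boundary pixels of the class-`cl` region: region pixels with a 4-neighbour
# outside the region; pixels on the image border count as boundary
class_boundary <- function(mask, cl) {
  r <- mask == cl
  if (!any(r)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  h <- nrow(r); w <- ncol(r)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- r
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  r & !interior
}

#' Boundary-F1 (BF) score for one class
#'
#' Contour-matching score: boundary precision is the fraction of predicted
#' boundary pixels lying within `tolerance` (Euclidean, pixels) of some true
#' boundary pixel, boundary recall the symmetric quantity, and the score
#' their harmonic mean.  The default tolerance is 0.75% of the image
#' diagonal, rounded up.  A class absent from both masks scores 1; absent
#' from exactly one, 0.
#'
#' @param pred,truth integer class grids of equal dimensions.
#' @param class class whose region boundary is scored.
#' @param tolerance match distance in pixels; `NULL` = 0.75% of diagonal.
#' @return scalar in `[0, 1]`.
#' @export
bf_score <- function(pred, truth, class = 1L, tolerance = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("`pred` and `truth` must have identical dimensions", call. = FALSE)
  if (is.null(tolerance))
    tolerance <- ceiling(0.0075 * sqrt(nrow(pred)^2 + ncol(pred)^2))
  in_pred <- any(pred == class); in_truth <- any(truth == class)
  if (!in_pred && !in_truth) return(1)
  if (xor(in_pred, in_truth)) return(0)
  bp <- which(class_boundary(pred, class), arr.ind = TRUE)
  bt <- which(class_boundary(truth, class), arr.ind = TRUE)
  frac_matched <- function(a, b) {
    # fraction of rows of `a` within tolerance of some row of `b`
    hit <- logical(nrow(a))
    chunk <- max(1L, 2^21 %/% nrow(b))     # bound the distance block size
    for (s in seq(1L, nrow(a), by = chunk)) {
      i <- s:min(nrow(a), s + chunk - 1L)
      d2 <- outer(a[i, 1], b[, 1], `-`)^2 + outer(a[i, 2], b[, 2], `-`)^2
      hit[i] <- matrixStats_rowMins(d2) <= tolerance^2
    }
    mean(hit)
  }
  precision <- frac_matched(bp, bt)
  recall <- frac_matched(bt, bp)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# row minima without extra deps
matrixStats_rowMins <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = FALSE))

#' Mean BF score over classes and slices
#'
#' Per-slice, per-class BF scores averaged first over the `C` classes of a
#' slice, then over slices.
#'
#' @param preds,truths lists of class grids (or single matrices).
#' @param C number of classes.
#' @param tolerance see [bf_score()].
#' @return scalar in `[0, 1]`.
#' @export
mean_bf_score <- function(preds, truths, C = 3L, tolerance = NULL) {
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths))
  per_slice <- mapply(function(p, t) {
    mean(vapply(seq_len(C) - 1L, function(cl) bf_score(p, t, cl, tolerance), 0))
  }, preds, truths)
  mean(per_slice)
}

#' Full metric report for predicted vs. true masks
#'
#' Accumulates one confusion matrix over all slices (micro aggregation) and
#' derives every reported quantity: per-class and mean-foreground Dice,
#' Jaccard, sensitivity, specificity, PPV, NPV; global/mean accuracy;
#' mean/weighted IoU; and the mean BF score.
#'
#' @param preds,truths lists of class grids (or single matrices).
#' @param C number of classes.
#' @param tolerance BF-score tolerance, see [bf_score()].
#' @return an object of class `metric_report`: list with `confusion`,
#'   `per_class`, `aggregate`, `dataset` and `mean_bf_score`.
#' @export
metric_report <- function(preds, truths, C = 3L, tolerance = NULL) {
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  cm <- Reduce(`+`, mapply(confusion_matrix, preds, truths,
                           MoreArgs = list(C = C), SIMPLIFY = FALSE))
  class(cm) <- c("confusion_matrix", "matrix", "array")
  seg <- segmentation_metrics(cm)
  structure(list(confusion = cm,
                 per_class = seg$per_class,
                 aggregate = seg$aggregate,
                 dataset = dataset_metrics(cm),
                 mean_bf_score = mean_bf_score(preds, truths, C, tolerance)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("<metric_report>\n\nPer-class metrics:\n")
  print(round(x$per_class, digits))
  cat("\nForeground means:\n")
  print(round(x$aggregate, digits))
  cat("\nDataset summaries:\n")
  print(round(c(x$dataset, mean_bf_score = x$mean_bf_score), digits))
  invisible(x)
}
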