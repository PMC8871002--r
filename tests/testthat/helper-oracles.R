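# Independent brute-force oracles and small fixtures used across tests.
# Everything here is deliberately written as plain loops / direct formulas,
# sharing no code with the package implementation.

# small phantom geometry that fits a 64 x 48 (or 16 x 16) grid
small_params <- function(height = 64L, width = 48L) {
  s <- min(1, min(height, width) / 48)   # shrink geometry for tiny grids
  phantom_params(height = height, width = width,
                 cavity_radius_range = c(6, 12) * s,
                 myo_thickness_range = c(3, 6) * s,
                 center_jitter = 3 * s, apical_shrink = 0.05)
}

tiny_params <- function() {
  phantom_params(height = 16L, width = 16L,
                 cavity_radius_range = c(2, 3),
                 myo_thickness_range = c(1, 2),
                 center_jitter = 0.5, apical_shrink = 0)
}

# random C-class mask pair with guaranteed class variety
random_mask_pair <- function(h, w, C) {
  list(pred = matrix(sample(0:(C - 1), h * w, replace = TRUE), h, w),
       truth = matrix(sample(0:(C - 1), h * w, replace = TRUE), h, w))
}

# ---- metric oracle: direct per-pixel formulas, no confusion matrix -------

oracle_class_metrics <- function(pred, truth, cl) {
  tp <- sum(pred == cl & truth == cl)
  fp <- sum(pred == cl & truth != cl)
  fn <- sum(pred != cl & truth == cl)
  tn <- sum(pred != cl & truth != cl)
  absent <- (tp + fn == 0) && (tp + fp == 0)
  r <- function(num, den) if (den > 0) num / den else if (absent) 1 else 0
  c(dice = r(2 * tp, 2 * tp + fp + fn),
    jaccard = r(tp, tp + fp + fn),
    sensitivity = r(tp, tp + fn),
    specificity = r(tn, tn + fp),
    ppv = r(tp, tp + fp),
    npv = r(tn, tn + fn))
}

oracle_dataset_metrics <- function(pred, truth, C) {
  n <- length(truth)
  recall <- iou <- share <- numeric(C)
  for (cl in 0:(C - 1)) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    absent <- (tp + fn == 0) && (tp + fp == 0)
    recall[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) else if (absent) 1 else 0
    iou[cl + 1] <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else if (absent) 1 else 0
    share[cl + 1] <- (tp + fn) / n
  }
  c(global_accuracy = sum(pred == truth) / n,
    mean_accuracy = mean(recall), mean_iou = mean(iou),
    weighted_iou = sum(share * iou))
}

# ---- boundary-F1 oracle: explicit loops, O(B^2) distances ----------------

oracle_boundary <- function(mask, cl) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != cl) next
    edge <- i == 1 || i == h || j == 1 || j == w
    nb <- c(if (i > 1) mask[i - 1, j], if (i < h) mask[i + 1, j],
            if (j > 1) mask[i, j - 1], if (j < w) mask[i, j + 1])
    if (edge || any(nb != cl)) out <- rbind(out, c(i, j))
  }
  out
}

oracle_bf_score <- function(pred, truth, cl, tol) {
  pin <- any(pred == cl); tin <- any(truth == cl)
  if (!pin && !tin) return(1)
  if (xor(pin, tin)) return(0)
  bp <- oracle_boundary(pred, cl)
  bt <- oracle_boundary(truth, cl)
  match_frac <- function(a, b) {
    # explicit loop over one side; plain arithmetic min over the other
    hits <- 0
    for (i in seq_len(nrow(a))) {
      best <- min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
      if (best <= tol) hits <- hits + 1
    }
    hits / nrow(a)
  }
  p <- match_frac(bp, bt); r <- match_frac(bt, bp)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# ---- nearest-neighbour resize oracle (explicit index mapping) ------------

oracle_nn_resize <- function(x, th, tw) {
  out <- matrix(x[1, 1], th, tw)
  for (i in seq_len(th)) for (j in seq_len(tw)) {
    si <- floor((i - 0.5) * nrow(x) / th + 0.5 + 0.5)  # round half up
    sj <- floor((j - 0.5) * ncol(x) / tw + 0.5 + 0.5)
    out[i, j] <- x[min(nrow(x), max(1, si)), min(ncol(x), max(1, sj))]
  }
  out
}
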