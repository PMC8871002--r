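#' Class-weighted cross-entropy loss
#'
#' Pixel-wise cross-entropy where each pixel contributes with the weight of
#' its true class, normalized by the total applied weight:
#' `L = -(sum_p w[t(p)] * log(prob_p[t(p)])) / sum_p w[t(p)]`.
#' The normalization makes the loss invariant to a common rescaling of the
#' weights and keeps its magnitude comparable across imbalance levels.
#' Probabilities are clipped at `1e-12` before the log so the loss stays
#' finite.
#'
#' @param probs probability tensor `(H, W, C, N)` (or `(H, W, C)` for a
#'   single slice), normalized over channels.
#' @param target integer class grid `(H, W, N)` / `(H, W)`, values in
#'   `[0, C)`.
#' @param weights a `class_weights` object or a plain numeric vector of
#'   length C.
#' @return scalar loss (non-negative).
#' @examples
#' p <- array(c(0.5, 0.5), c(1, 1, 2))
#' weighted_cross_entropy(p, matrix(0L, 1, 1), c(1, 1))   # log(2)
#' @export
weighted_cross_entropy <- function(probs, target, weights) {
  w <- if (inherits(weights, "class_weights")) weights$weights else weights
  d <- dim(probs)
  if (length(d) == 3L) dim(probs) <- d <- c(d[1], d[2], d[3], 1L)
  C <- d[3]
  if (length(w) != C) stop("`weights` must have length C", call. = FALSE)
  tg <- as.integer(target)
  if (length(tg) != d[1] * d[2] * d[4])
    stop("`target` does not match the probability tensor's pixel count",
         call. = FALSE)
  if (any(tg < 0L | tg >= C))
    stop(sprintf("target classes must lie in [0, %d)", C), call. = FALSE)
  m <- chan_mat(probs)                       # (H*W*N) x C
  pt <- m[cbind(seq_along(tg), tg + 1L)]
  wt <- w[tg + 1L]
  sw <- sum(wt)
  if (sw <= 0) stop("total applied weight is zero", call. = FALSE)
  -sum(wt * log(pmax(pt, 1e-12))) / sw
}

# loss + gradient w.r.t. logits for softmax + weighted cross-entropy:
# dL/dz[p, c] = w[t(p)] * (prob[p, c] - 1{c == t(p)}) / sum_p w[t(p)]
wce_logits_grad <- function(probs, target, weights) {
  w <- if (inherits(weights, "class_weights")) weights$weights else weights
  d <- dim(probs)
  tg <- as.integer(target)
  m <- chan_mat(probs)
  wt <- w[tg + 1L]
  sw <- sum(wt)
  g <- m
  g[cbind(seq_along(tg), tg + 1L)] <- g[cbind(seq_along(tg), tg + 1L)] - 1
  g <- g * (wt / sw)
  loss <- -sum(wt * log(pmax(m[cbind(seq_along(tg), tg + 1L)], 1e-12))) / sw
  list(loss = loss, dz = unchan_mat(g, d))
}

#' Mini-batch pixel accuracy
#'
#' Percentage of pixels whose argmax prediction equals the target class —
#' the "mini-batch accuracy" traced during training.
#'
#' @inheritParams weighted_cross_entropy
#' @return percentage in `[0, 100]`.
#' @export
minibatch_accuracy <- function(probs, target) {
  d <- dim(probs)
  if (length(d) == 3L) dim(probs) <- c(d[1], d[2], d[3], 1L)
  cls <- argmax_classes(probs)
  100 * mean(as.integer(cls) == as.integer(target))
}
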