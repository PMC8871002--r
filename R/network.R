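# Network instantiation and forward/backward passes.
#
# Activations are (H, W, C, N) arrays.  The convolutional kernels live in
# src/conv_ops.cpp; batch normalization, ReLU and softmax are plain R.

#' Instantiate the FCN with seeded initialization
#'
#' Allocates every learnable tensor of the architecture (He-uniform weights,
#' zero biases, unit batch-norm scale, zero offset) from a seeded generator,
#' so the same `(spec, seed)` always yields identical initial parameters.
#'
#' @param spec an [fcn_spec()].
#' @param seed integer initialization seed.
#' @return an object of class `fcn_network`: list with `spec`, `params`
#'   (named list of arrays), `bn` (running statistics per batch-norm layer),
#'   and `seed`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fcn_spec"))
  forward_shapes(spec)   # re-validates shape chaining
  f <- spec$filters; C <- spec$num_classes
  he <- function(dims, fan_in) {
    lim <- sqrt(6 / fan_in)
    array(runif(prod(dims), -lim, lim), dims)
  }
  params <- with_seed(seed, list(
    conv1_w = he(c(3, 3, 1, f[1]), 9 * 1),
    conv1_b = numeric(f[1]),
    bn1_gamma = rep(1, f[1]), bn1_beta = numeric(f[1]),
    conv2_w = he(c(3, 3, f[1], f[2]), 9 * f[1]),
    conv2_b = numeric(f[2]),
    bn2_gamma = rep(1, f[2]), bn2_beta = numeric(f[2]),
    conv3_w = he(c(3, 3, f[2], f[3]), 9 * f[2]),
    conv3_b = numeric(f[3]),
    bn3_gamma = rep(1, f[3]), bn3_beta = numeric(f[3]),
    tconv_w = he(c(4, 4, f[4], f[3]), 16 * f[3]),
    tconv_b = numeric(f[4]),
    conv4_w = he(c(3, 3, f[4], C), 9 * f[4]),
    conv4_b = numeric(C)))
  bn <- lapply(f[1:3], function(k)
    list(mean = numeric(k), var = rep(1, k)))
  structure(list(spec = spec, params = params, bn = bn,
                 bn_eps = 1e-5, bn_momentum = 0.1, seed = as.integer(seed)),
            class = "fcn_network")
}

#' @export
print.fcn_network <- function(x, ...) {
  cat(sprintf("<fcn_network> input %s, %d classes, %s parameters, seed %d\n",
              paste(x$spec$input_shape, collapse = "x"), x$spec$num_classes,
              format(count_learnables(x$spec), big.mark = ","), x$seed))
  invisible(x)
}

# ---- layer helpers -------------------------------------------------------

relu_fw <- function(x) {
  x[x < 0] <- 0
  x
}

# channel axis is the 3rd of (H, W, C, N); reshape to (H*W*N) x C
chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
unchan_mat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

bn_fw <- function(x, gamma, beta, state, eps, momentum, training) {
  d <- dim(x)
  m <- chan_mat(x)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(inv, each = nrow(m))
  y <- xhat * rep(gamma, each = nrow(m)) + rep(beta, each = nrow(m))
  list(y = unchan_mat(y, d), xhat = xhat, inv = inv, state = state)
}

bn_bw <- function(dy, cache, gamma) {
  d <- dim(dy)
  dm <- chan_mat(dy)
  n <- nrow(dm)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  # dx = gamma*inv * (dy - mean(dy) - xhat * mean(dy*xhat))   (batch stats)
  t1 <- rep(dbeta / n, each = n)
  t2 <- xhat * rep(dgamma / n, each = n)
  dx <- (dm - t1 - t2) * rep(gamma * cache$inv, each = n)
  list(dx = unchan_mat(dx, d), dgamma = dgamma, dbeta = dbeta)
}

softmax_fw <- function(z) {
  d <- dim(z)
  m <- chan_mat(z)
  m <- m - do.call(pmax, as.data.frame(m))
  e <- exp(m)
  p <- e / rowSums(e)
  unchan_mat(p, d)
}

# ---- full passes ---------------------------------------------------------

# forward pass; returns logits, probabilities and (optionally) caches for
# the backward pass.  `training` switches batch-norm between batch and
# running statistics; running stats are updated in the returned `bn`.
fcn_forward <- function(net, x, training = FALSE, keep_cache = training) {
  p <- net$params
  c1 <- .conv2d_fw(x, p$conv1_w, p$conv1_b)
  b1 <- bn_fw(c1, p$bn1_gamma, p$bn1_beta, net$bn[[1]], net$bn_eps,
              net$bn_momentum, training)
  r1 <- relu_fw(b1$y)
  mp <- .maxpool_fw(r1)
  c2 <- .conv2d_fw(mp$y, p$conv2_w, p$conv2_b)
  b2 <- bn_fw(c2, p$bn2_gamma, p$bn2_beta, net$bn[[2]], net$bn_eps,
              net$bn_momentum, training)
  r2 <- relu_fw(b2$y)
  c3 <- .conv2d_fw(r2, p$conv3_w, p$conv3_b)
  b3 <- bn_fw(c3, p$bn3_gamma, p$bn3_beta, net$bn[[3]], net$bn_eps,
              net$bn_momentum, training)
  r3 <- relu_fw(b3$y)
  t1 <- .tconv_fw(r3, p$tconv_w, p$tconv_b)
  z <- .conv2d_fw(t1, p$conv4_w, p$conv4_b)
  probs <- softmax_fw(z)
  cache <- if (keep_cache)
    list(x = x, b1 = b1, r1 = r1, mp = mp, b2 = b2, r2 = r2, b3 = b3,
         r3 = r3, t1 = t1)
  else NULL
  list(logits = z, probs = probs, cache = cache,
       bn = list(b1$state, b2$state, b3$state))
}

# backward pass from dL/dlogits; returns gradients named like net$params
fcn_backward <- function(net, cache, dz) {
  p <- net$params
  g4 <- .conv2d_bw(cache$t1, p$conv4_w, dz)
  gt <- .tconv_bw(cache$r3, p$tconv_w, g4$dx)
  d_r3 <- gt$dx * (cache$r3 > 0)
  gb3 <- bn_bw(d_r3, cache$b3, p$bn3_gamma)
  g3 <- .conv2d_bw(cache$r2, p$conv3_w, gb3$dx)
  d_r2 <- g3$dx * (cache$r2 > 0)
  gb2 <- bn_bw(d_r2, cache$b2, p$bn2_gamma)
  g2 <- .conv2d_bw(cache$mp$y, p$conv2_w, gb2$dx)
  d_mp <- .maxpool_bw(cache$mp$idx, g2$dx, dim(cache$r1))
  d_r1 <- d_mp * (cache$r1 > 0)
  gb1 <- bn_bw(d_r1, cache$b1, p$bn1_gamma)
  g1 <- .conv2d_bw(cache$x, p$conv1_w, gb1$dx)
  list(conv1_w = g1$dw, conv1_b = g1$db,
       bn1_gamma = gb1$dgamma, bn1_beta = gb1$dbeta,
       conv2_w = g2$dw, conv2_b = g2$db,
       bn2_gamma = gb2$dgamma, bn2_beta = gb2$dbeta,
       conv3_w = g3$dw, conv3_b = g3$db,
       bn3_gamma = gb3$dgamma, bn3_beta = gb3$dbeta,
       tconv_w = gt$dw, tconv_b = gt$db,
       conv4_w = g4$dw, conv4_b = g4$db)
}

# images (0..255) to the network input tensor, scaled to [0, 1]
images_to_tensor <- function(images) {
  if (is.matrix(images)) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]] / 255
  x
}

# per-pixel argmax over channels; ties go to the lowest class index
argmax_classes <- function(probs) {
  d <- dim(probs)
  m <- chan_mat(probs)
  cls <- max.col(m, ties.method = "first") - 1L
  out <- array(cls, c(d[1], d[2], d[4]))
  out
}

#' Predict a class mask for one image
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics) and takes the per-pixel argmax over the softmax channels,
#' ties broken towards the lowest class index.  The image must match the
#' network's input size exactly; no silent resizing.
#'
#' @param network an [build_network()] result (typically after [train()]).
#' @param image integer matrix, 0..255, of the spec's input height x width.
#' @return integer class matrix of the same size.
#' @export
predict_mask <- function(network, image) {
  stopifnot(inherits(network, "fcn_network"))
  if (!is.matrix(image) ||
      !identical(dim(image), as.integer(network$spec$input_shape[1:2])))
    stop(sprintf("image must be %s, got %s (no silent resize)",
                 paste(network$spec$input_shape[1:2], collapse = " x "),
                 paste(dim(image), collapse = " x ")), call. = FALSE)
  fw <- fcn_forward(network, images_to_tensor(image), training = FALSE)
  matrix(argmax_classes(fw$probs)[, , 1L], nrow(image), ncol(image))
}

#' Predict class masks for a list of slices
#'
#' @param network an `fcn_network`.
#' @param slices list of `labeled_slice` objects (only `$image` is used).
#' @return list of integer class matrices.
#' @export
predict_masks <- function(network, slices) {
  lapply(slices, function(s) predict_mask(network, s$image))
}
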