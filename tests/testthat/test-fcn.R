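# Architecture conformance and the network's numerical behaviour.

test_that("the spec validates its architectural contract", {
  expect_error(fcn_spec(conv_kernel = 5), "3x3")
  expect_error(fcn_spec(pool_size = 3), "2x2")
  expect_error(fcn_spec(tconv_kernel = 2), "4x4")
  expect_error(fcn_spec(input_shape = c(255, 192, 1)), "even")
  expect_error(fcn_spec(num_classes = 1), "num_classes")
  kinds <- vapply(fcn_spec()$layers, `[[`, "", "kind")
  expect_identical(kinds, c("input", "convolution", "batch_norm", "relu",
                            "max_pool", "convolution", "batch_norm", "relu",
                            "convolution", "batch_norm", "relu",
                            "transpose_convolution", "convolution",
                            "softmax", "pixel_classification"))
})

test_that("activation shapes propagate as published", {
  sh <- forward_shapes(fcn_spec(num_classes = 2))
  expect_identical(sh[[1]], c(256L, 192L, 1L))
  expect_identical(sh[[2]], c(256L, 192L, 16L))
  expect_identical(sh[[5]], c(128L, 96L, 16L))
  expect_identical(sh[[6]], c(128L, 96L, 32L))
  expect_identical(sh[[9]], c(128L, 96L, 64L))
  expect_identical(sh[[12]], c(256L, 192L, 16L))  # documented shape fix
  expect_identical(sh[[13]], c(256L, 192L, 2L))
  expect_identical(sh[[14]], c(256L, 192L, 2L))
  expect_identical(sh[[15]], c(256L, 192L))
  # shape-propagation oracle at a different input size
  sh64 <- forward_shapes(fcn_spec(input_shape = c(64, 64, 1)))
  expect_identical(sh64[[5]], c(32L, 32L, 16L))
  expect_identical(sh64[[14]], c(64L, 64L, 3L))
})

test_that("learnable tensors and their total match the published table", {
  ls <- learnable_shapes(fcn_spec(num_classes = 2))
  expect_identical(ls$conv1_weights, c(3L, 3L, 1L, 16L))
  expect_identical(ls$conv2_weights, c(3L, 3L, 16L, 32L))
  expect_identical(ls$conv3_weights, c(3L, 3L, 32L, 64L))
  expect_identical(ls$tconv_weights, c(4L, 4L, 16L, 64L))
  expect_identical(ls$conv4_weights, c(3L, 3L, 16L, 2L))
  expect_identical(ls$conv4_bias, c(1L, 1L, 2L))
  expect_identical(count_learnables(fcn_spec(num_classes = 2)), 40210)
  # brute-force oracle: sum of element counts of the printed tensors
  oracle <- (3 * 3 * 1 * 16 + 16) + (16 + 16) + (3 * 3 * 16 * 32 + 32) +
    (32 + 32) + (3 * 3 * 32 * 64 + 64) + (64 + 64) +
    (4 * 4 * 16 * 64 + 16) + (3 * 3 * 16 * 2 + 2)
  expect_identical(count_learnables(fcn_spec(num_classes = 2)), oracle)
  # fully convolutional: count independent of spatial input size
  expect_identical(count_learnables(fcn_spec(input_shape = c(64, 64, 1))),
                   count_learnables(fcn_spec()))
})

test_that("initialization is deterministic in the seed", {
  spec <- fcn_spec(input_shape = c(16, 16, 1), filters = c(2, 3, 4, 2))
  n1 <- build_network(spec, seed = 7)
  n2 <- build_network(spec, seed = 7)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(spec, seed = 8)
  expect_false(identical(n1$params, n3$params))
})

test_that("output keeps the input's spatial size for any even input", {
  for (hw in list(c(16, 16), c(24, 16), c(64, 48))) {
    spec <- fcn_spec(input_shape = c(hw, 1), filters = c(2, 2, 2, 2))
    net <- build_network(spec, seed = 1)
    img <- matrix(sample(0:255, prod(hw), TRUE), hw[1], hw[2])
    m <- predict_mask(net, img)
    expect_identical(dim(m), as.integer(hw))
    expect_true(all(m %in% 0:2))
  }
})

test_that("softmax channels are normalized and argmax matches a pixel loop", {
  spec <- fcn_spec(input_shape = c(8, 8, 1), filters = c(2, 3, 4, 2))
  net <- build_network(spec, seed = 2)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  fw <- saxfcn:::fcn_forward(net, x)
  sums <- apply(fw$probs[, , , 1], c(1, 2), sum)
  expect_equal(sums, matrix(1, 8, 8), tolerance = 1e-6)
  cls <- predict_mask(net, matrix(as.integer(x * 255), 8, 8))
  for (i in 1:8) for (j in 1:8) {
    p <- fw$probs[i, j, , 1]
    expect_identical(cls[i, j], which(p == max(p))[1] - 1L)
  }
})

test_that("forced final-layer logits yield an all-background mask", {
  spec <- fcn_spec(input_shape = c(16, 16, 1), filters = c(2, 3, 4, 2))
  net <- build_network(spec, seed = 3)
  net$params$conv4_w[] <- 0
  net$params$conv4_b <- c(10, 0, 0)
  m <- predict_mask(net, matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_true(all(m == 0L))
  # ties break toward the lowest class index
  net$params$conv4_b <- c(0, 0, 0)
  expect_true(all(predict_mask(net, matrix(128L, 16, 16)) == 0L))
})

test_that("predict_mask refuses wrong input sizes instead of resizing", {
  net <- build_network(fcn_spec(input_shape = c(16, 16, 1),
                                filters = c(2, 2, 2, 2)), seed = 1)
  expect_error(predict_mask(net, matrix(0L, 32, 32)), "no silent resize")
})

test_that("conv and transpose-conv kernels match naive R oracles", {
  set.seed(30)
  naive_conv <- function(x, w, b) {
    d <- dim(x); kd <- dim(w); ph <- (kd[1] - 1) / 2
    y <- array(0, c(d[1], d[2], kd[4], d[4]))
    for (n in 1:d[4]) for (co in 1:kd[4]) for (i in 1:d[1]) for (j in 1:d[2]) {
      acc <- b[co]
      for (ci in 1:d[3]) for (ki in 1:kd[1]) for (kj in 1:kd[2]) {
        si <- i + ki - 1 - ph; sj <- j + kj - 1 - ph
        if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2])
          acc <- acc + x[si, sj, ci, n] * w[ki, kj, ci, co]
      }
      y[i, j, co, n] <- acc
    }
    y
  }
  naive_tconv <- function(x, w, b) {
    d <- dim(x); Co <- dim(w)[3]
    yf <- array(0, c(2 * d[1] + 2, 2 * d[2] + 2, Co, d[4]))
    for (n in 1:d[4]) for (ci in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2])
      for (co in 1:Co) for (ki in 1:4) for (kj in 1:4)
        yf[2 * (i - 1) + ki, 2 * (j - 1) + kj, co, n] <-
          yf[2 * (i - 1) + ki, 2 * (j - 1) + kj, co, n] +
          x[i, j, ci, n] * w[ki, kj, co, ci]
    y <- yf[2:(2 * d[1] + 1), 2:(2 * d[2] + 1), , , drop = FALSE]
    for (co in 1:Co) y[, , co, ] <- y[, , co, ] + b[co]
    y
  }
  x <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)); b <- rnorm(4)
  expect_equal(saxfcn:::.conv2d_fw(x, w, b), naive_conv(x, w, b),
               tolerance = 1e-12)
  tw <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)); tb <- rnorm(3)
  expect_equal(saxfcn:::.tconv_fw(x, tw, tb), naive_tconv(x, tw, tb),
               tolerance = 1e-12)
})
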