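# Loss, solvers and the training loop.

test_that("weighted cross-entropy reproduces hand-computed values", {
  p1 <- array(c(1, 0, 0), c(1, 1, 3))
  expect_equal(weighted_cross_entropy(p1, matrix(0L, 1, 1), c(5, 1, 1)), 0)
  p2 <- array(c(0.5, 0.25, 0.25), c(1, 1, 3))
  expect_equal(weighted_cross_entropy(p2, matrix(0L, 1, 1), rep(1, 3)), log(2))
  # weight-scale invariance of the normalized loss
  set.seed(40)
  pr <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  for (n in 1:2) for (i in 1:4) for (j in 1:4)
    pr[i, j, , n] <- pr[i, j, , n] / sum(pr[i, j, , n])
  tg <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  w <- c(0.4, 3, 2)
  expect_equal(weighted_cross_entropy(pr, tg, w),
               weighted_cross_entropy(pr, tg, 2 * w))
  # weighting the true classes of a known tensor, by hand
  expect_gt(weighted_cross_entropy(pr, tg, w), 0)
  expect_error(weighted_cross_entropy(pr, tg[, 1:3, ], w), "pixel count")
  expect_error(weighted_cross_entropy(pr, tg, c(1, 1)), "length C")
})

test_that("loss gradient w.r.t. logits matches central finite differences", {
  set.seed(41)
  for (C in c(2, 4)) {
    z <- array(rnorm(2 * 2 * C), c(2, 2, C, 1))
    tg <- array(sample(0:(C - 1), 4, TRUE), c(2, 2, 1))
    w <- runif(C, 0.2, 3)
    probs <- saxfcn:::softmax_fw(z)
    an <- saxfcn:::wce_logits_grad(probs, tg, w)
    eps <- 1e-6
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- z[i] + eps
      zm <- z; zm[i] <- z[i] - eps
      lp <- weighted_cross_entropy(saxfcn:::softmax_fw(zp), tg, w)
      lm <- weighted_cross_entropy(saxfcn:::softmax_fw(zm), tg, w)
      fd <- (lp - lm) / (2 * eps)
      expect_equal(an$dz[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("whole-network parameter gradients pass a finite-difference check", {
  spec <- fcn_spec(input_shape = c(8, 8, 1), num_classes = 3,
                   filters = c(2, 3, 4, 2))
  net <- build_network(spec, seed = 5)
  set.seed(42)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(sample(0:2, 128, TRUE), c(8, 8, 2))
  w <- c(0.4, 3, 2.5)
  fw <- saxfcn:::fcn_forward(net, x, training = TRUE)
  lg <- saxfcn:::wce_logits_grad(fw$probs, y, w)
  gr <- saxfcn:::fcn_backward(net, fw$cache, lg$dz)
  eps <- 1e-5
  lossat <- function(n) {
    f <- saxfcn:::fcn_forward(n, x, training = TRUE)
    weighted_cross_entropy(f$probs, y, w)
  }
  for (nm in names(net$params)) {
    pv <- net$params[[nm]]
    for (i in sample(length(pv), min(3, length(pv)))) {
      n1 <- net; n1$params[[nm]][i] <- pv[i] + eps
      n2 <- net; n2$params[[nm]][i] <- pv[i] - eps
      fd <- (lossat(n1) - lossat(n2)) / (2 * eps)
      rel <- abs(fd - gr[[nm]][i]) / max(1e-6, abs(fd) + abs(gr[[nm]][i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("mini-batch accuracy equals a brute-force pixel loop", {
  set.seed(43)
  pr <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  tg <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  acc <- minibatch_accuracy(pr, tg)
  hits <- 0
  for (n in 1:2) for (i in 1:4) for (j in 1:4)
    hits <- hits + (which.max(pr[i, j, , n]) - 1L == tg[i, j, n])
  expect_equal(acc, 100 * hits / 32)
  perfect <- array(0, c(2, 2, 3, 1)); tgp <- array(1L, c(2, 2, 1))
  perfect[, , 2, ] <- 1
  expect_equal(minibatch_accuracy(perfect, tgp), 100)
  # all-background prediction on a 90%-background mask scores 90%
  pr0 <- array(0, c(10, 10, 3, 1)); pr0[, , 1, ] <- 1
  m <- matrix(0L, 10, 10); m[1, 1:10] <- 1L
  expect_equal(minibatch_accuracy(pr0, array(m, c(10, 10, 1))), 90)
})

test_that("training history has the stated shape and is deterministic", {
  d <- generate_dataset(8, tiny_params(), seed = 60, split = c(train = 1))
  spec <- fcn_spec(input_shape = c(16, 16, 1), filters = c(2, 3, 4, 2))
  cfg <- train_config("adam", 0.01, epochs = 2, mini_batch = 4, seed = 61)
  f1 <- train(build_network(spec, seed = 62), d$slices, cfg)
  expect_identical(nrow(f1$history), 4L)    # ceil(8/4) * 2
  expect_identical(attr(f1$history, "iters_per_epoch"), 2)
  f2 <- train(build_network(spec, seed = 62), d$slices, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$network$params, f2$network$params)
  # odd batch split: 5 slices, mini-batch 2 -> 3 iterations/epoch
  f3 <- train(build_network(spec, seed = 62), d$slices[1:5],
              train_config("sgdm", 0.01, epochs = 1, mini_batch = 2, seed = 0))
  expect_identical(nrow(f3$history), 3L)
  expect_error(train(build_network(spec, 1), list(), cfg), "non-empty")
})

test_that("a zero learning rate leaves parameters unchanged", {
  d <- generate_dataset(4, tiny_params(), seed = 70, split = c(train = 1))
  spec <- fcn_spec(input_shape = c(16, 16, 1), filters = c(2, 2, 2, 2))
  for (sv in c("sgdm", "adam", "rmsprop")) {
    net <- build_network(spec, seed = 71)
    fit <- train(net, d$slices,
                 train_config(sv, 0, epochs = 1, mini_batch = 4, seed = 72))
    expect_identical(fit$network$params, net$params)
    # and at LR -> 0 the change is vanishingly small (continuity)
    fit2 <- train(net, d$slices,
                  train_config(sv, 1e-12, epochs = 1, mini_batch = 4, seed = 72))
    delta <- max(abs(unlist(fit2$network$params) - unlist(net$params)))
    expect_lt(delta, 1e-9)
  }
})

test_that("a short Adam run reduces the loss on phantom data", {
  d <- generate_dataset(16, small_params(32L, 32L), seed = 80,
                        split = c(train = 1))
  spec <- fcn_spec(input_shape = c(32, 32, 1))
  net <- build_network(spec, seed = 81)
  fit <- train(net, d$slices,
               train_config("adam", 0.001, epochs = 3, mini_batch = 4,
                            seed = 82))
  es <- epoch_summary(fit$history)
  expect_lt(es$loss[3], es$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(fit$history$loss >= 0))
})

test_that("the sweep produces one row per grid point, deterministically", {
  d <- generate_dataset(6, tiny_params(), seed = 90, split = c(train = 1))
  spec <- fcn_spec(input_shape = c(16, 16, 1), filters = c(2, 2, 2, 2))
  tab <- hyperparameter_sweep(d$slices, solvers = c("adam", "sgdm"),
                              learning_rates = 0.01, epochs = 1L,
                              mini_batches = 4L, spec = spec, seed = 91)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$solver, c("adam", "sgdm"))
  tab2 <- hyperparameter_sweep(d$slices, solvers = c("adam", "sgdm"),
                               learning_rates = 0.01, epochs = 1L,
                               mini_batches = 4L, spec = spec, seed = 91)
  expect_identical(tab, tab2)
})
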