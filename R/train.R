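#' Training configuration
#'
#' Bundles the solver and its hyper-parameters.  The three supported solvers
#' are stochastic gradient descent with momentum (`"sgdm"`, momentum 0.9),
#' `"adam"` (beta 0.9/0.999, eps 1e-8) and `"rmsprop"` (decay 0.99,
#' eps 1e-8) — the standard defaults for each.  The reference operating
#' point for the segmentation task is Adam at learning rate 0.001 with
#' mini-batch 4.
#'
#' @param solver one of `"sgdm"`, `"adam"`, `"rmsprop"`.
#' @param learning_rate positive step size.
#' @param epochs number of passes over the training data (>= 1).
#' @param mini_batch mini-batch size (>= 1); the last batch of an epoch may
#'   be smaller.
#' @param seed seed controlling shuffling (and any solver randomness).
#' @param momentum SGDM momentum coefficient.
#' @param shuffle reshuffle the training order every epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(solver = c("adam", "sgdm", "rmsprop"),
                         learning_rate = 0.001, epochs = 150L,
                         mini_batch = 4L, seed = 1L, momentum = 0.9,
                         shuffle = TRUE) {
  solver <- match.arg(solver)
  assert_scalar_num(learning_rate, "learning_rate", lower = 0)
  assert_scalar_num(epochs, "epochs", lower = 1)
  assert_scalar_num(mini_batch, "mini_batch", lower = 1)
  structure(list(solver = solver, learning_rate = learning_rate,
                 epochs = as.integer(epochs), mini_batch = as.integer(mini_batch),
                 seed = as.integer(seed), momentum = momentum,
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

solver_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })  # shape-preserving
  list(v = zeros, m = zeros, s = zeros, t = 0L)
}

solver_step <- function(params, grads, state, config) {
  lr <- config$learning_rate
  switch(config$solver,
    sgdm = {
      for (k in names(params)) {
        state$v[[k]] <- config$momentum * state$v[[k]] - lr * grads[[k]]
        params[[k]] <- params[[k]] + state$v[[k]]
      }
    },
    adam = {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      state$t <- state$t + 1L
      for (k in names(params)) {
        state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
        state$s[[k]] <- b2 * state$s[[k]] + (1 - b2) * grads[[k]]^2
        mhat <- state$m[[k]] / (1 - b1^state$t)
        shat <- state$s[[k]] / (1 - b2^state$t)
        params[[k]] <- params[[k]] - lr * mhat / (sqrt(shat) + eps)
      }
    },
    rmsprop = {
      decay <- 0.99; eps <- 1e-8
      for (k in names(params)) {
        state$s[[k]] <- decay * state$s[[k]] + (1 - decay) * grads[[k]]^2
        params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(state$s[[k]]) + eps)
      }
    },
    stop("unknown solver: ", config$solver))
  list(params = params, state = state)
}

#' Train the FCN with class-weighted cross-entropy
#'
#' Standard mini-batch loop: per epoch the training order is (optionally)
#' reshuffled with a seed derived from `config$seed`, the batch is run
#' forward (batch-norm in batch-statistics mode), the weighted
#' cross-entropy loss and pixel accuracy are recorded, and the parameters
#' are updated by the configured solver.  Identical
#' `(network, slices, config, weights)` give identical histories.
#'
#' @param network an [build_network()] result.
#' @param slices non-empty list of `labeled_slice` objects (images must
#'   match the network input size).
#' @param config a [train_config()].
#' @param weights class weights for the loss; default: inverse-frequency
#'   weights computed from the masks of `slices`.
#' @return list with `network` (trained) and `history` (data frame with one
#'   row per iteration: epoch, iteration, loss, accuracy, lr).
#' @export
train <- function(network, slices, config = train_config(),
                  weights = NULL) {
  stopifnot(inherits(network, "fcn_network"), inherits(config, "train_config"))
  if (!is.list(slices) || length(slices) == 0L)
    stop("`slices` must be a non-empty list of labeled slices", call. = FALSE)
  C <- network$spec$num_classes
  if (is.null(weights))
    weights <- inverse_frequency_weights(
      class_frequencies(lapply(slices, `[[`, "mask"), C), C)
  wvec <- if (inherits(weights, "class_weights")) weights$weights else weights

  n <- length(slices)
  mb <- config$mini_batch
  iters_per_epoch <- ceiling(n / mb)
  imgs <- lapply(slices, `[[`, "image")
  msks <- lapply(slices, `[[`, "mask")

  state <- solver_init(network$params)
  hist <- vector("list", config$epochs * iters_per_epoch)
  it <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle)
      with_seed(config$seed + epoch, sample.int(n))
    else seq_len(n)
    for (b in seq_len(iters_per_epoch)) {
      idx <- ord[((b - 1L) * mb + 1L):min(b * mb, n)]
      x <- images_to_tensor(imgs[idx])
      y <- array(0L, c(dim(x)[1], dim(x)[2], length(idx)))
      for (j in seq_along(idx)) y[, , j] <- msks[[idx[j]]]

      fw <- fcn_forward(network, x, training = TRUE)
      network$bn <- fw$bn
      lg <- wce_logits_grad(fw$probs, y, wvec)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d iteration %d", epoch, b),
             call. = FALSE)
      acc <- minibatch_accuracy(fw$probs, y)
      grads <- fcn_backward(network, fw$cache, lg$dz)
      st <- solver_step(network$params, grads, state, config)
      network$params <- st$params
      state <- st$state

      it <- it + 1L
      hist[[it]] <- data.frame(epoch = epoch, iteration = it,
                               loss = lg$loss, accuracy = acc,
                               lr = config$learning_rate)
    }
  }
  history <- do.call(rbind, hist)
  attr(history, "wall_time") <- proc.time()[["elapsed"]] - t0
  attr(history, "iters_per_epoch") <- iters_per_epoch
  list(network = network, history = history)
}

#' Per-epoch aggregates of a training history
#'
#' @param history the `history` data frame returned by [train()].
#' @return data frame with one row per epoch (mean loss, mean accuracy).
#' @export
epoch_summary <- function(history) {
  agg <- stats::aggregate(history[, c("loss", "accuracy")],
                          by = list(epoch = history$epoch), FUN = mean)
  agg[order(agg$epoch), ]
}

#' Hyper-parameter sweep over solver, learning rate, epochs and batch size
#'
#' Trains one network per grid combination (fresh seeded initialization
#' each time) and tabulates the final mini-batch accuracy plus, when
#' validation slices are given, held-out mean foreground Dice.  This mirrors
#' the solver-comparison experiment: solvers {SGDM, Adam, RMSProp} crossed
#' with learning rates, epoch budgets and mini-batch sizes.
#'
#' @param train_slices training slices.
#' @param solvers,learning_rates,epochs,mini_batches grid axes.
#' @param spec network specification, default [fcn_spec()].
#' @param val_slices optional held-out slices for Dice evaluation.
#' @param seed seed used for every run (initialization and shuffling), so
#'   rows differ only in their hyper-parameters.
#' @param weights optional class weights (default: from `train_slices`).
#' @return data frame with one row per combination; CSV-ready.
#' @export
hyperparameter_sweep <- function(train_slices,
                                 solvers = c("sgdm", "adam", "rmsprop"),
                                 learning_rates = c(0.01, 0.001),
                                 epochs = c(30L, 50L, 100L, 150L),
                                 mini_batches = c(4L, 8L),
                                 spec = fcn_spec(), val_slices = NULL,
                                 seed = 1L, weights = NULL) {
  grid <- expand.grid(solver = solvers, learning_rate = learning_rates,
                      epochs = epochs, mini_batch = mini_batches,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty hyper-parameter grid", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- train_config(solver = g$solver, learning_rate = g$learning_rate,
                        epochs = g$epochs, mini_batch = g$mini_batch,
                        seed = seed)
    net <- build_network(spec, seed = seed)
    fit <- train(net, train_slices, cfg, weights = weights)
    last_epoch <- fit$history[fit$history$epoch == g$epochs, ]
    out <- data.frame(g,
                      final_accuracy = mean(last_epoch$accuracy),
                      final_loss = mean(last_epoch$loss))
    if (!is.null(val_slices)) {
      rep <- metric_report(predict_masks(fit$network, val_slices),
                           lapply(val_slices, `[[`, "mask"),
                           C = spec$num_classes)
      out$val_dice_fg <- unname(rep$aggregate["dice"])
      out$val_mean_iou <- unname(rep$dataset["mean_iou"])
    }
    out
  })
  do.call(rbind, rows)
}
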