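test_that("confusion matrices count pixels by (truth, prediction)", {
  truth <- matrix(c(0L, 0L, 1L, 2L), 2, 2, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE)
  cm <- confusion_matrix(pred, truth, 3)
  expect_equal(unclass(cm)[cbind(c(1, 1, 2, 3), c(1, 2, 2, 2))], c(1, 1, 1, 1),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  # perfect prediction -> diagonal with trace = pixel count
  cmd <- confusion_matrix(truth, truth, 3)
  expect_equal(sum(diag(cmd)), 4)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # additivity: accumulating slices = matrix of the concatenation
  t2 <- matrix(sample(0:2, 16, TRUE), 4, 4)
  p2 <- matrix(sample(0:2, 16, TRUE), 4, 4)
  both <- confusion_matrix(rbind(pred, p2[1:2, 1:2]),
                           rbind(truth, t2[1:2, 1:2]), 3)
  expect_equal(unclass(confusion_matrix(pred, truth, 3) +
                         confusion_matrix(p2[1:2, 1:2], t2[1:2, 1:2], 3)),
               unclass(both), ignore_attr = TRUE)
  expect_error(confusion_matrix(pred, t2), "identical dimensions")
})

test_that("binary one-vs-rest counts reduce the confusion matrix correctly", {
  truth <- matrix(c(0L, 0L, 1L, 2L), 2, 2, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE)
  cm <- confusion_matrix(pred, truth, 3)
  expect_equal(binary_counts(cm, 1), c(TP = 1, FP = 2, FN = 0, TN = 1))
  for (cl in 0:2) expect_equal(sum(binary_counts(cm, cl)), sum(cm))
  cmd <- confusion_matrix(truth, truth, 3)
  for (cl in 0:2) {
    b <- binary_counts(cmd, cl)
    expect_equal(unname(b[c("FP", "FN")]), c(0, 0))
  }
})

test_that("segmentation metrics reproduce hand-worked counts", {
  # TP=8, FP=1, FN=1 for class 1
  truth <- matrix(0L, 4, 4); truth[1:3, 1:3] <- 1L
  pred <- truth
  pred[1, 1] <- 0L            # one miss (FN)
  pred[4, 4] <- 1L            # one false alarm (FP)
  sm <- segmentation_metrics(confusion_matrix(pred, truth, 2))
  r1 <- sm$per_class[sm$per_class$class == 1, ]
  expect_equal(r1$dice, 16 / 18)
  expect_equal(r1$jaccard, 8 / 10)
  expect_equal(r1$sensitivity, 8 / 9)
  expect_equal(r1$ppv, 8 / 9)
  # perfect prediction -> all ones; disjoint -> zeros
  perf <- segmentation_metrics(confusion_matrix(truth, truth, 2))
  expect_true(all(perf$per_class[, -1] == 1))
  disj <- matrix(0L, 4, 4); disj[4, 4] <- 1L
  dm <- segmentation_metrics(confusion_matrix(disj, truth, 2))$per_class
  expect_equal(unlist(dm[dm$class == 1, c("dice", "jaccard", "sensitivity", "ppv")]),
               c(dice = 0, jaccard = 0, sensitivity = 0, ppv = 0))
})

test_that("dataset metrics match hand arithmetic, including absent classes", {
  cm <- matrix(c(90, 10, 0, 0), 2, 2, byrow = TRUE)
  class(cm) <- c("confusion_matrix", class(cm))
  dm <- dataset_metrics(cm)
  expect_equal(unname(dm["global_accuracy"]), 0.9)
  expect_equal(unname(dm["mean_iou"]), (0.9 + 0) / 2)
  expect_equal(unname(dm["weighted_iou"]), 0.9)    # class-1 share is 0
  # equal shares collapse weighted IoU onto mean IoU
  cm2 <- matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE)
  class(cm2) <- c("confusion_matrix", class(cm2))
  d2 <- dataset_metrics(cm2)
  expect_equal(unname(d2["weighted_iou"]), unname(d2["mean_iou"]))
  # diagonal -> all four are 1
  cm3 <- confusion_matrix(matrix(0:2, 1), matrix(0:2, 1), 3)
  expect_equal(unname(dataset_metrics(cm3)), rep(1, 4))
})

test_that("dice and jaccard obey their algebraic identity", {
  set.seed(50)
  for (i in 1:20) {
    mp <- random_mask_pair(12, 12, 3)
    sm <- segmentation_metrics(confusion_matrix(mp$pred, mp$truth, 3))$per_class
    expect_equal(sm$dice, 2 * sm$jaccard / (1 + sm$jaccard), tolerance = 1e-12)
    expect_true(all(sm$jaccard <= sm$dice + 1e-15))
  }
})

test_that("per-class metrics are invariant under label permutation", {
  set.seed(51)
  mp <- random_mask_pair(10, 10, 3)
  perm <- c(2L, 0L, 1L)   # class k -> perm[k+1]
  pp <- matrix(perm[mp$pred + 1L], 10, 10)
  pt <- matrix(perm[mp$truth + 1L], 10, 10)
  a <- segmentation_metrics(confusion_matrix(mp$pred, mp$truth, 3))$per_class
  b <- segmentation_metrics(confusion_matrix(pp, pt, 3))$per_class
  for (cl in 0:2)
    expect_equal(a[a$class == cl, -1], b[b$class == perm[cl + 1] + 1 - 1, -1],
                 ignore_attr = TRUE)
  ga <- dataset_metrics(confusion_matrix(mp$pred, mp$truth, 3))["global_accuracy"]
  gb <- dataset_metrics(confusion_matrix(pp, pt, 3))["global_accuracy"]
  expect_equal(ga, gb)
})

test_that("bf_score matches its conventions and the O(B^2) oracle", {
  truth <- matrix(0L, 20, 20); truth[5:12, 5:12] <- 1L
  expect_equal(bf_score(truth, truth, 1), 1)
  # absent-class conventions
  bg <- matrix(0L, 20, 20)
  expect_equal(bf_score(bg, bg, 1), 1)
  expect_equal(bf_score(truth, bg, 1), 0)
  expect_equal(bf_score(bg, truth, 1), 0)
  # 1-pixel shift within tolerance 2 -> perfect score
  shift1 <- matrix(0L, 20, 20); shift1[6:13, 5:12] <- 1L
  expect_equal(bf_score(shift1, truth, 1, tolerance = 2), 1)
  expect_equal(bf_score(shift1, truth, 1, tolerance = 2),
               oracle_bf_score(shift1, truth, 1, 2))
  # shift beyond tolerance: score < 1 and equal to the all-pairs oracle
  tol <- 2
  shift <- matrix(0L, 20, 20); shift[(5 + tol + 2):(12 + tol + 2), 5:12] <- 1L
  s <- bf_score(shift, truth, 1, tolerance = tol)
  expect_lt(s, 1)
  expect_equal(s, oracle_bf_score(shift, truth, 1, tol))
  # symmetry
  expect_equal(bf_score(shift, truth, 1, tol), bf_score(truth, shift, 1, tol))
})

test_that("the default BF tolerance is 0.75% of the diagonal, rounded up", {
  truth <- matrix(0L, 256, 192); truth[100:140, 80:120] <- 1L
  # diag = 320 -> tol = ceiling(2.4) = 3: a 3-pixel shift still matches
  shift <- matrix(0L, 256, 192); shift[103:143, 80:120] <- 1L
  expect_equal(bf_score(shift, truth, 1), 1)
  shift7 <- matrix(0L, 256, 192); shift7[107:147, 80:120] <- 1L
  expect_lt(bf_score(shift7, truth, 1), 1)
})

test_that("metric_report assembles micro-accumulated metrics and mean BF", {
  set.seed(52)
  preds <- truths <- list()
  for (k in 1:3) {
    mp <- random_mask_pair(12, 12, 3)
    preds[[k]] <- mp$pred; truths[[k]] <- mp$truth
  }
  rep <- metric_report(preds, truths, C = 3, tolerance = 2)
  expect_s3_class(rep, "metric_report")
  pooled <- Reduce(`+`, mapply(confusion_matrix, preds, truths,
                               MoreArgs = list(C = 3), SIMPLIFY = FALSE))
  expect_equal(sum(rep$confusion), sum(pooled))
  expect_true(all(rep$per_class[, -1] >= 0 & rep$per_class[, -1] <= 1))
  bf <- mean(vapply(1:3, function(k)
    mean(vapply(0:2, function(cl)
      oracle_bf_score(preds[[k]], truths[[k]], cl, 2), 0)), 0))
  expect_equal(rep$mean_bf_score, bf)
})
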