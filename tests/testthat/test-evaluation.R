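# Confusion matrices, PRF, ROC/AUC, aggregation, trade-off score.

test_that("confusion counts and derived accuracy follow the definitions", {
  cm <- confusion(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0), 2)
  expect_equal(unclass(cm), matrix(c(1L, 1L, 1L, 2L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 5)
  perfect <- confusion(0:2, 0:2, 3)
  expect_true(all(perfect == diag(3)))
  expect_error(confusion(0:2, 0:1, 3), "equal length")
  expect_error(confusion(integer(0), integer(0), 3), "no records")
  expect_error(confusion(c(0, 3), c(0, 0), 3), "0..2")
})

test_that("the binary external-validation arithmetic reproduces itself", {
  # integer confusion implied by precision 0.986 / recall 0.973 on 80/73
  cm <- confusion(rep(c(0L, 1L), c(80, 73)),
                  c(rep(0L, 79), 1L, rep(1L, 71), 0L, 0L), 2,
                  c("normal", "abnormal"))
  expect_equal(unclass(cm), matrix(c(79L, 2L, 1L, 71L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(diag(cm)) / sum(cm), 150 / 153)
  expect_equal(round(100 * sum(diag(cm)) / sum(cm), 2), 98.04)
  prf <- per_class_prf(cm)
  expect_equal(round(prf$precision[2], 3), 0.986)
  expect_equal(round(prf$recall[2], 3), 0.973)
  expect_equal(round(prf$f1[2], 3), 0.979)
})

test_that("per-class metrics handle perfection and zero denominators", {
  prf <- per_class_prf(confusion(0:2, 0:2, 3))
  expect_equal(prf$precision, rep(1, 3))
  expect_equal(prf$f1, rep(1, 3))
  # an always-class-0 predictor: recall 1 for class 0, 0 elsewhere
  expect_warning(prf0 <- per_class_prf(confusion(c(0, 1, 2), c(0, 0, 0), 3)),
                 "precision")
  expect_equal(prf0$recall, c(1, 0, 0))
  expect_equal(prf0$f1[2:3], c(0, 0))
})

test_that("macro and weighted F1 aggregate as documented", {
  agg <- aggregate_f1(c(1, 0), c(3, 1))
  expect_equal(agg$macro_f1, 0.5)
  expect_equal(agg$weighted_f1, 0.75)
  f1 <- c(0.98, 0.93, 0.79, 0.96, 0.88, 0.92, 0.97, 0.91, 1.00)
  expect_equal(aggregate_f1(f1)$macro_f1, 0.926, tolerance = 0.001)
  expect_equal(aggregate_f1(rep(1, 4), rep(2, 4))$weighted_f1, 1)
})

test_that("rank-statistic AUC matches hand-counted concordance", {
  s <- matrix(c(0.9, 0.8, 0.4, 0.3, 0.1, 0.2, 0.6, 0.7), ncol = 2)
  r <- roc_auc(s, c(0L, 0L, 1L, 1L))
  expect_equal(r$per_class$auc[1], 1.0)    # perfect separation
  expect_equal(r$per_class$auc[2], 1.0)
  r2 <- roc_auc(matrix(c(0.9, 0.4, 0.8, 0.3), ncol = 1), c(0L, 0L, 1L, 1L))
  # positives are class 0 = scores 0.9, 0.4; negatives 0.8, 0.3
  expect_equal(r2$per_class$auc[1], 0.75)
  # inverted labels on a perfect ranking give AUC 0
  r3 <- roc_auc(matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1), c(0L, 0L, 1L, 1L))
  expect_equal(r3$per_class$auc[1], 0)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    sc <- matrix(runif(n), ncol = 1)
    y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE)) # both classes present
    a1 <- roc_auc(sc, y)$per_class$auc[1]
    a2 <- roc_auc(exp(3 * sc) - 1, y)$per_class$auc[1]
    expect_equal(a1, a2)
  }
})

test_that("classes without positives are excluded from the macro mean", {
  sc <- matrix(runif(12), 4, 3)
  expect_warning(r <- roc_auc(sc, c(0L, 0L, 1L, 1L)), "undefined")
  expect_true(is.na(r$per_class$auc[3]))
  expect_false(is.na(r$macro_auc))
})

test_that("ROC curves rise monotonically from (0,0) to (1,1)", {
  set.seed(5)
  r <- roc_auc(matrix(runif(20), ncol = 1), rep(c(0L, 1L), 10))
  cv <- r$curves[[1]]
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("cross-validation aggregation reports mean and sample sd", {
  folds <- data.frame(accuracy = c(97.2, 97.4, 96.9, 97.4, 97.1),
                      cross_entropy = c(0.082, 0.079, 0.085, 0.081, 0.083))
  s <- cv_aggregate(folds)
  expect_equal(s$mean[s$metric == "accuracy"], 97.2)
  expect_equal(s$mean[s$metric == "cross_entropy"], 0.082)
  expect_equal(s$sd[s$metric == "cross_entropy"], sd(folds$cross_entropy))
  same <- data.frame(m = rep(0.5, 4))
  expect_equal(cv_aggregate(same)$sd, 0)
  expect_error(cv_aggregate(folds[1, , drop = FALSE]), "two folds")
})

test_that("the accuracy-complexity score behaves at its anchors", {
  expect_equal(normalized_score(0.9, 2e6, 0.9, 2e6)$score, 1)
  expect_equal(normalized_score(0.45, 2e6, 0.9, 2e6, weight = 1)$score, 0.5)
  # published comparative inputs for the densely connected reference
  s <- normalized_score(95.46, 7.9e6, 96.52, 1.9e6, weight = 0.5)
  expect_equal(s$score, 0.6148, tolerance = 1e-4)
})

test_that("full evaluation reports are internally consistent", {
  set.seed(6)
  m <- build_bone_cnn(tiny_arch(input_size = 32L, num_classes = 9L,
                                input_channels = 3L))
  d <- phantom_batch(36, size = 32L, seed = 31)
  rep <- evaluate_model(m, d, paste0("C", 0:8))
  expect_equal(rep$top1_error, 1 - rep$accuracy)
  expect_equal(sum(rep$per_class$support), 36)
  expect_equal(rep$macro_f1, mean(rep$per_class$f1))
  expect_gte(rep$macro_f1, min(rep$per_class$f1))
  expect_lte(rep$macro_f1, max(rep$per_class$f1))
  expect_equal(sum(rep$confusion), 36)
  # untrained model sits near chance: binomial 99% interval around 1/9
  p <- 1 / 9; n <- 36
  expect_lt(abs(rep$accuracy - p), 2.58 * sqrt(p * (1 - p) / n) + 1e-9)
  # confusion-derived accuracy equals the direct label-match fraction
  pred <- predict(m, d$x, type = "class")
  expect_equal(rep$accuracy, mean(pred == d$y))
  out <- tempfile()
  write_eval_report(rep, out)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "confusion.csv")))
  js <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(js$accuracy, rep$accuracy)
})
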