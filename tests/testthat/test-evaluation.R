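test_that("stratified 5-fold split of 85/35 gives 17+7 validation folds", {
  labels <- stats::setNames(c(rep("correct", 85), rep("incorrect", 35)),
                            sprintf("j%03d", 1:120))
  fs <- stratified_kfold(labels, k = 5, rng_seed = 1)
  for (f in 1:5) {
    val <- names(fs$assignments)[fs$assignments == f]
    expect_length(val, 24)
    expect_equal(sum(labels[val] == "correct"), 17)
    expect_equal(sum(labels[val] == "incorrect"), 7)
  }
  # partition: union of folds is the dataset, pairwise disjoint
  expect_setequal(names(fs$assignments), names(labels))
  expect_true(all(table(fs$assignments) == 24))
})

test_that("stratified split balances classes within one and errors when impossible", {
  labels <- stats::setNames(c(rep(0, 13), rep(1, 7)), letters[1:20])
  fs <- stratified_kfold(labels, k = 4, rng_seed = 2)
  per_fold <- table(factor(fs$assignments, levels = 1:4),
                    labels[names(fs$assignments)])
  expect_true(all(abs(per_fold[, "0"] - 13 / 4) < 1))
  expect_true(all(abs(per_fold[, "1"] - 7 / 4) < 1))
  expect_error(stratified_kfold(labels, k = 8), "cannot fill")
  expect_error(stratified_kfold(labels, k = 1), ">= 2")
})

test_that("confusion matrix counts with positive = incorrectly seated", {
  cm <- confusion(c("correct", "incorrect"), c("correct", "incorrect"))
  expect_equal(cm$FP + cm$FN, 0)
  cm2 <- confusion(c("incorrect", "correct"), c("correct", "incorrect"))
  expect_equal(unlist(cm2[c("TP", "FN", "FP", "TN")]),
               c(TP = 0L, FN = 1L, FP = 1L, TN = 0L))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "mismatch")
  # pooling 5 folds of 24 covers all 120
  folds <- replicate(5, confusion(rep(c(0, 1), c(17, 7)),
                                  rep(c(0, 1), c(17, 7))),
                     simplify = FALSE)
  pooled <- pool_confusion(folds)
  expect_equal(with(pooled, TP + TN + FP + FN), 120)
})

test_that("the six metric formulas are computed exactly", {
  cm <- structure(list(TP = 30L, FP = 19L, TN = 66L, FN = 5L),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 96 / 120)
  expect_equal(m$precision_ppv, 30 / 49)
  expect_equal(m$npv, 66 / 71)
  expect_equal(m$f1, 60 / 84)
  expect_equal(m$sensitivity, 30 / 35)
  expect_equal(m$specificity, 66 / 85)
  # identities: sensitivity * n_pos = TP, specificity * n_neg = TN
  expect_equal(m$sensitivity * 35, 30)
  expect_equal(m$specificity * 85, 66)
  # perfect and symmetric matrices
  perfect <- compute_metrics(structure(list(TP = 10L, FP = 0L, TN = 10L,
                                            FN = 0L),
                                       class = "confusion_matrix"))
  expect_true(all(unlist(perfect) == 1))
  half <- compute_metrics(structure(list(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
                                    class = "confusion_matrix"))
  expect_true(all(unlist(half) == 0.5))
  # zero denominator -> undefined, not 0
  none <- compute_metrics(structure(list(TP = 0L, FP = 0L, TN = 5L, FN = 5L),
                                    class = "confusion_matrix"))
  expect_true(is.na(none$precision_ppv))
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(11)
  for (i in 1:20) {
    cm <- structure(as.list(stats::setNames(sample(1:50, 4, TRUE),
                                            c("TP", "FP", "TN", "FN"))),
                    class = "confusion_matrix")
    m <- compute_metrics(cm)
    npos <- cm$TP + cm$FN; nneg <- cm$TN + cm$FP
    expect_equal(m$accuracy,
                 (m$sensitivity * npos + m$specificity * nneg) / (npos + nneg))
  }
})

test_that("rank AUC is correct on separated, null and tied data", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)    # tie -> midrank
  set.seed(12)
  conf <- runif(10000); y <- rbinom(10000, 1, 0.3)    # independent
  expect_equal(roc_auc(conf, y), 0.5, tolerance = 0.02)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rank and trapezoid AUC agree to 1e-9 on random instances", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    conf <- round(runif(n), sample(1:3, 1))   # induce ties
    expect_equal(roc_auc(conf, y), roc_auc_trapezoid(conf, y),
                 tolerance = 1e-9)
  }
})

test_that("rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(48, 1, 0.3))
    conf <- runif(50)
    expect_equal(roc_auc(conf, y),
                 as.numeric(pROC::auc(pROC::roc(y, conf, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("the printed-metrics confusion matrix is recovered uniquely", {
  cm <- recover_confusion_matrix(0.86, 0.78, 35, 85)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 30L, FN = 5L, FP = 19L, TN = 66L))
  m <- compute_metrics(cm)
  expect_equal(round_half_up(m$accuracy), 0.80)
  expect_equal(round_half_up(m$precision_ppv), 0.61)
  expect_equal(round_half_up(m$npv), 0.93)
  expect_equal(round_half_up(m$f1), 0.71)
  trivial <- recover_confusion_matrix(1.00, 1.00, 10, 10)
  expect_equal(c(trivial$TP, trivial$TN), c(10L, 10L))
  expect_equal(c(trivial$FP, trivial$FN), c(0L, 0L))
  # 0.50 on 3 positives has no integer solution
  expect_error(recover_confusion_matrix(0.50, 0.50, 3, 3), "no integer")
})

test_that("round_half_up rounds .5 upward at 2 decimals", {
  expect_equal(round_half_up(0.615), 0.62)
  expect_equal(round_half_up(0.625), 0.63)   # R's round() would give 0.62
  expect_equal(round_half_up(0.6249), 0.62)
})
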