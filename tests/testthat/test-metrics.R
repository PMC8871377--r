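test_that("confusion matrices count correctly, including the published UCSD test split", {
  cm <- confusion_matrix(c(rep("AMD", 3), rep("NORMAL", 2)),
                         c(rep("AMD", 3), rep("NORMAL", 2)))
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 3, FN = 0, FP = 0, TN = 2))

  inverted <- confusion_matrix(c(rep("AMD", 3), rep("NORMAL", 2)),
                               c(rep("NORMAL", 3), rep("AMD", 2)))
  expect_equal(unlist(inverted[c("TP", "FN", "FP", "TN")]),
               c(TP = 0, FN = 3, FP = 2, TN = 0))

  # 500 AMD all correct, 1 of 250 normals called AMD
  truth <- c(rep("AMD", 500), rep("NORMAL", 250))
  est <- c(rep("AMD", 500), "AMD", rep("NORMAL", 249))
  ucsd <- confusion_matrix(truth, est)
  expect_equal(unlist(ucsd[c("TP", "FN", "FP", "TN")]),
               c(TP = 500, FN = 0, FP = 1, TN = 249))

  expect_error(confusion_matrix("AMD", c("AMD", "NORMAL")), "length")
  expect_error(confusion_matrix("DME", "AMD"), "unknown label")
})

test_that("per-class and weighted metrics reproduce both published tables cell by cell", {
  r2 <- function(x) round_half_up(x, 2)

  ucsd <- new_confusion_matrix(TP = 500, FN = 0, FP = 1, TN = 249)
  per <- class_metrics(ucsd)
  amd <- per[per$class == "AMD", ]; nor <- per[per$class == "NORMAL", ]
  expect_equal(r2(c(amd$accuracy, amd$sensitivity, amd$precision, amd$f1)),
               c(100.00, 100.00, 99.80, 99.90))
  expect_equal(r2(c(nor$accuracy, nor$sensitivity, nor$precision, nor$f1)),
               c(99.60, 99.60, 100.00, 99.80))
  wt <- weighted_metrics(ucsd)
  expect_equal(r2(c(wt$accuracy, wt$sensitivity, wt$precision, wt$f1)),
               rep(99.87, 4))
  expect_equal(r2(global_accuracy(ucsd)), 99.87)

  duke <- new_confusion_matrix(TP = 687, FN = 36, FP = 16, TN = 1391)
  per <- class_metrics(duke)
  amd <- per[per$class == "AMD", ]; nor <- per[per$class == "NORMAL", ]
  expect_equal(r2(c(amd$accuracy, amd$sensitivity, amd$precision, amd$f1)),
               c(95.02, 95.02, 97.72, 96.35))
  expect_equal(r2(c(nor$accuracy, nor$sensitivity, nor$precision, nor$f1)),
               c(98.86, 98.86, 97.48, 98.17))
  wt <- weighted_metrics(duke)
  expect_equal(r2(c(wt$accuracy, wt$sensitivity, wt$precision)),
               rep(97.56, 3))
  expect_equal(r2(wt$f1), 97.55)

  balanced <- new_confusion_matrix(10, 0, 0, 10)
  expect_equal(unlist(weighted_metrics(balanced)), rep(100, 4),
               ignore_attr = TRUE)
})

test_that("metric identities hold exactly on integer counts", {
  set.seed(21)
  for (i in 1:25) {
    cts <- sample(0:40, 4, replace = TRUE)
    if (cts[1] + cts[2] == 0 || cts[3] + cts[4] == 0) next
    cm <- new_confusion_matrix(cts[1], cts[2], cts[3], cts[4])
    per <- class_metrics(cm)
    amd <- per[per$class == "AMD", ]
    if (cm$TP + cm$FN > 0) {
      expect_equal(amd$sensitivity, 100 * cm$TP / (cm$TP + cm$FN))
    }
    if (cm$TP + cm$FP > 0) {
      expect_equal(amd$precision, 100 * cm$TP / (cm$TP + cm$FP))
    } else {
      expect_true(is.na(amd$precision))
    }
    expect_equal(global_accuracy(cm),
                 100 * (cm$TP + cm$TN) / sum(unlist(cm)))
    # binary identity: support-weighted recall equals overall accuracy
    expect_equal(weighted_metrics(cm)$accuracy, global_accuracy(cm))
  }
})

test_that("zero-denominator metrics are reported absent, never zero by fiat", {
  cm <- new_confusion_matrix(TP = 0, FN = 5, FP = 0, TN = 5)
  per <- class_metrics(cm)
  expect_true(is.na(per$precision[per$class == "AMD"]))
  expect_true(is.na(per$f1[per$class == "AMD"]))
  expect_error(weighted_metrics(new_confusion_matrix(0, 0, 2, 3)), "support")
})

test_that("trapezoidal AUC equals all-pairs counting and the pROC reference, with tie credit", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1),
                       c("AMD", "AMD", "NORMAL", "NORMAL", "NORMAL")), 1)

  set.seed(31)
  big <- 4000
  null_auc <- roc_auc(rnorm(big),
                      sample(c("AMD", "NORMAL"), big, replace = TRUE))
  expect_lt(abs(null_auc - 0.5), 0.05)

  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(8:30, 1)
    truth <- sample(c("AMD", "NORMAL"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(1:6, n, replace = TRUE) + 0  # heavy ties
    expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth))
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("NORMAL", "AMD"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, truth), proc_auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  truth <- sample(c("AMD", "NORMAL"), 60, replace = TRUE)
  scores <- rnorm(60) + (truth == "AMD")
  base <- roc_auc(scores, truth)
  expect_equal(roc_auc(exp(scores), truth), base)
  expect_equal(roc_auc(scores^3 + 5 * scores, truth), base)
})

test_that("ROC curve runs from (0,0) to (1,1) with grouped ties", {
  rc <- roc_curve(c(3, 2, 2, 1), c("AMD", "AMD", "NORMAL", "NORMAL"))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_equal(nrow(rc), 4)  # Inf + 3 distinct thresholds
  expect_error(roc_curve(1:3, rep("AMD", 3)), "both classes")
})

test_that("report tidying rounds at the reporting layer only", {
  truth <- c(rep("AMD", 500), rep("NORMAL", 250))
  est <- c(rep("AMD", 500), "AMD", rep("NORMAL", 249))
  rep <- metrics_report(truth, est, scores = c(rep(2, 500), 2, rep(1, 249)))
  td <- tidy(rep)
  expect_equal(td$accuracy, c(100.00, 99.60, 99.87))
  expect_equal(td$f1, c(99.90, 99.80, 99.87))
  # unrounded values retained in the report itself
  expect_gt(abs(rep$weighted$accuracy - 99.87), 1e-6)
  gl <- glance(rep)
  expect_equal(gl$n, 750)
  # single-class input: AUC absent
  solo <- metrics_report(rep("AMD", 5), rep("AMD", 5), scores = 1:5)
  expect_true(is.na(solo$auc))
  expect_null(solo$weighted)
})

test_that("half-up rounding breaks ties upward at reporting precision", {
  expect_equal(round_half_up(99.865, 2), 99.87)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(0.99997, 4), 1)
  expect_equal(round_half_up(-2.5, 0), -3)
})
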