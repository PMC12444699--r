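test_that("MAPE is the median absolute percentage error with explicit zero policy", {
  expect_equal(mape(3, 4)$mape, 25.0)
  ## APE set {25, 50, 100}: odd-count median is 50
  expect_equal(mape(c(3, 3, 2), c(4, 2, 1))$mape, 50.0)
  expect_equal(mape(c(2, 5, 1), c(2, 5, 1))$mape, 0.0)

  ## zero-day handling: the zero-actual day is dropped and counted
  r <- mape(c(9, 3), c(0, 4))
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$mape, 25.0)
  r2 <- mape(c(1, 2, 3), c(0, 2, 3), zero_policy = "denominator-max-1")
  expect_equal(r2$n_excluded, 0L)
  expect_equal(r2$mape, median(c(100, 0, 0)))
  expect_error(mape(c(1, 2), c(0, 0)), "undefined")

  ## permutation invariance
  set.seed(131)
  p <- runif(50, 1, 5); a <- rpois(50, 3) + 1
  o <- sample(50)
  expect_equal(mape(p, a)$mape, mape(p[o], a[o])$mape)
})

test_that("interval coverage counts inclusive endpoints", {
  expect_equal(interval_coverage(rep(1, 5), rep(5, 5), rep(3, 5)), 100)
  expect_equal(interval_coverage(c(1, 1), c(3, 3), c(3, 0)), 50)
  ## an actual exactly on an endpoint is covered
  expect_equal(interval_coverage(2, 4, 4), 100)
  expect_equal(interval_coverage(2, 4, 2), 100)
  expect_error(interval_coverage(c(3, 1), c(2, 2), c(1, 1)), "elementwise")
  ## permutation invariance
  set.seed(132)
  lo <- rnorm(40); hi <- lo + 2; a <- lo + runif(40, -1, 3)
  o <- sample(40)
  expect_equal(interval_coverage(lo, hi, a),
               interval_coverage(lo[o], hi[o], a[o]))
})

test_that("ROC curves are monotone and AUC matches the pair-enumeration oracle", {
  ## perfect separation
  curve <- roc_curve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  expect_equal(auc_ci(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1.0)
  expect_equal(head(c(curve$fpr, curve$tpr), 1), 0)
  expect_true(all(diff(curve$tpr) >= 0) && all(diff(curve$fpr) >= 0))
  expect_equal(c(tail(curve$fpr, 1), tail(curve$tpr, 1)), c(1, 1))

  ## six scores with a tie, hand-enumerable
  s6 <- c(1, 2, 2, 3, 4, 5); l6 <- c(F, F, T, F, T, T)
  expect_equal(auc_ci(s6, l6)$auc, auc_pairs_oracle(s6, l6))

  ## exact agreement with exhaustive enumeration for n <= 200, with ties
  set.seed(133)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    labels <- runif(n) < plogis(scores - 2.5)
    if (all(labels) || !any(labels)) next
    expect_equal(auc_ci(scores, labels)$auc, auc_pairs_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC and the DeLong interval agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(134)
  scores <- rnorm(150) + rep(c(0, 1), c(100, 50))
  labels <- rep(c(FALSE, TRUE), c(100, 50))
  ours <- auc_ci(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ref_ci[c(1, 3)], tolerance = 1e-6)
})

test_that("uninformative scores give chance-level AUC and near-zero Youden J", {
  set.seed(135)
  scores <- rnorm(2000)
  labels <- runif(2000) < 0.3
  a <- auc_ci(scores, labels)
  expect_lt(abs(a$auc - 0.5), 0.05)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  yp <- youden_point(roc_curve(scores, labels))
  expect_lt(abs(yp$j), 0.1)
})

test_that("the Youden point maximizes J, breaks ties, and lies on the curve", {
  curve <- roc_curve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))
  yp <- youden_point(curve)
  expect_equal(yp$j, 1)
  expect_equal(yp$sensitivity, 1)
  expect_equal(yp$specificity, 1)
  i <- which(curve$thresholds == yp$threshold)
  expect_equal(curve$tpr[i], yp$sensitivity)
  expect_equal(1 - curve$fpr[i], yp$specificity)

  ## two thresholds with equal J: the higher-sensitivity one wins
  s <- c(1, 2, 3, 4); l <- c(F, T, F, T)
  ypt <- youden_point(roc_curve(s, l))
  expect_equal(ypt$sensitivity, 1)
  expect_equal(ypt$threshold, 2)
})

test_that("confusion metrics use safe division", {
  all1 <- confusion_metrics(c(T, F, T, F), c(T, F, T, F))
  expect_equal(unlist(all1[c("ppv", "npv", "sensitivity", "specificity")]),
               c(ppv = 1, npv = 1, sensitivity = 1, specificity = 1))

  ## hand-built table: TP 4, FP 10, FN 1, TN 350
  flags <- c(rep(TRUE, 14), rep(FALSE, 351))
  labels <- c(rep(TRUE, 4), rep(FALSE, 10), TRUE, rep(FALSE, 350))
  cm <- confusion_metrics(flags, labels)
  expect_equal(cm$ppv, 4 / 14)
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$npv, 350 / 351)
  expect_equal(cm$specificity, 35 / 36)

  ## no positive labels: sensitivity undefined, not zero
  cm2 <- confusion_metrics(c(F, F, T), c(F, F, F))
  expect_true(is.na(cm2$sensitivity))
  expect_equal(cm2$specificity, 2 / 3)
})

test_that("metrics_report assembles reproducible per-model rows", {
  set.seed(136)
  n <- 120
  actual <- rnbinom(n, size = 5, mu = 2)
  tbl <- rbind(
    data.frame(date = as.Date("2023-01-01") + 0:(n - 1), model = "good",
               actual = actual, point = actual + rnorm(n, sd = 0.5)),
    data.frame(date = as.Date("2023-01-01") + 0:(n - 1), model = "bad",
               actual = actual, point = rnorm(n, 2)))
  tbl$lo95 <- tbl$point - 3; tbl$hi95 <- tbl$point + 3
  thr <- observed_threshold(actual, 0.9)
  rep1 <- metrics_report(tbl, thr)
  rep2 <- metrics_report(tbl, thr)
  expect_identical(rep1, rep2)
  expect_setequal(rep1$model, c("good", "bad"))
  good <- rep1[rep1$model == "good", ]
  bad <- rep1[rep1$model == "bad", ]
  expect_lt(good$mape, bad$mape)
  expect_gt(good$auc, bad$auc)
  expect_true(all(c("coverage", "ppv", "npv", "sensitivity", "specificity",
                    "auc_lo", "auc_hi", "cal_threshold") %in% names(rep1)))
  expect_true(good$auc_lo <= good$auc && good$auc <= good$auc_hi)
})
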