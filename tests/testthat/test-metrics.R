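test_that("threshold-dependent measures reproduce hand-checked confusion tables", {
  cc <- confusion_counts(TP = 144, TN = 149, FP = 26, FN = 31)
  expect_equal(sensitivity(cc), 100 * 144 / 175, tolerance = 1e-12)
  expect_equal(round(sensitivity(cc), 2), 82.29)
  expect_equal(round(specificity(cc), 2), 85.14)
  expect_equal(round(accuracy(cc), 2), 83.71)
  expect_equal(round(mcc(cc), 2), 0.67)
  cc2 <- confusion_counts(TP = 175, TN = 9, FP = 166, FN = 0)
  expect_equal(round(specificity(cc2), 2), 5.14)
  expect_equal(round(accuracy(cc2), 2), 52.57)
  expect_equal(round(mcc(cc2), 2), 0.16)
  expect_equal(sensitivity(confusion_counts(5, 0, 0, 0)), 100)
  expect_equal(specificity(confusion_counts(0, 7, 0, 0)), 100)
  expect_true(is.nan(sensitivity(confusion_counts(0, 3, 2, 0))))
})

test_that("confusion counting respects the >= threshold rule", {
  s <- c(0.9, 0.8, 0.3, 0.1)
  lab <- c("positive", "negative", "positive", "negative")
  cc <- confusion_at_threshold(s, lab, 0.5)
  expect_equal(unlist(cc), c(TP = 1, TN = 1, FP = 1, FN = 1))
  cc_inf <- confusion_at_threshold(s, lab, Inf)
  expect_equal(cc_inf$TP + cc_inf$FP, 0)
  cc_all <- confusion_at_threshold(rep(1, 3), rep("positive", 3), 0)
  expect_equal(cc_all$FP + cc_all$FN, 0)
  expect_error(confusion_at_threshold(1:3, c(TRUE, FALSE), 0), "length")
  # raising the threshold never increases predicted positives
  set.seed(4)
  sc <- rnorm(50)
  npos <- vapply(sort(unique(sc)), function(t) sum(sc >= t), 0)
  expect_true(all(diff(npos) <= 0))
})

test_that("MCC is symmetric under class swap and negates under prediction flip", {
  set.seed(7)
  for (i in 1:20) {
    v <- sample(0:40, 4, replace = TRUE)
    a <- confusion_counts(v[1], v[2], v[3], v[4])
    swapped <- confusion_counts(v[2], v[1], v[4], v[3])
    flipped <- confusion_counts(v[3], v[4], v[1], v[2])
    expect_equal(mcc(a), mcc(swapped), tolerance = 1e-12)
    expect_equal(mcc(a), -mcc(flipped), tolerance = 1e-12)
  }
  expect_equal(mcc(confusion_counts(10, 10, 0, 0)), 1)
  expect_equal(mcc(confusion_counts(0, 0, 10, 10)), -1)
  expect_equal(mcc(confusion_counts(5, 0, 5, 0)), 0)  # degenerate -> 0
})

test_that("accuracy equals the class-size-weighted mean of sen and spc", {
  set.seed(8)
  for (i in 1:20) {
    v <- sample(1:40, 4)
    cc <- confusion_counts(v[1], v[2], v[3], v[4])
    P <- v[1] + v[4]; N <- v[2] + v[3]
    expect_equal(accuracy(cc),
                 (sensitivity(cc) * P + specificity(cc) * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("AUROC equals brute-force pair counting, matches pROC, and nulls at 0.5", {
  expect_equal(auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    sc <- round(rnorm(n), 1)  # rounding forces ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    expect_equal(auroc(sc, lab), oracle_auroc(sc, lab), tolerance = 1e-12)
  }
  sc <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  expect_equal(auroc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  set.seed(10)
  big <- rnorm(1000)
  expect_equal(auroc(big, sample(rep(c(TRUE, FALSE), 500))), 0.5,
               tolerance = 0.05)
  expect_error(auroc(1:3, rep(TRUE, 3)), "both classes")
})

test_that("threshold sweep exposes the accuracy-maximising default threshold", {
  s <- c(0.9, 0.7, 0.6, 0.2, 0.4, 0.1)
  lab <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  tab <- threshold_sweep(s, lab)
  expect_equal(nrow(tab), length(unique(s)))
  thr <- attr(tab, "default_threshold")
  cc <- confusion_at_threshold(s, lab, thr)
  expect_equal(accuracy(cc), max(tab$acc))
})

test_that("cross-validation is exact on a separable toy and null on permuted labels", {
  toy <- separable_toy(25, seed = 11)
  folds <- rep(1:5, 10)
  cv <- cross_validate(toy$x, toy$labels, folds,
                       model_spec("linear_margin", c = 10), seed = 12)
  expect_equal(unname(cv$mean["acc"]), 100)
  # per-fold counts partition the full set
  tot <- sum(vapply(cv$per_fold, function(e) {
    with(e$counts, TP + TN + FP + FN)
  }, 0))
  expect_equal(tot, nrow(toy$x))
  set.seed(13)
  perm <- sample(toy$labels)
  cv0 <- cross_validate(toy$x, perm, folds, model_spec("linear_margin"),
                        seed = 14)
  expect_lt(abs(cv0$mean[["acc"]] - 50), 25)
})
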