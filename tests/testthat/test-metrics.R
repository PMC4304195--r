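test_that("confusion counts treat disordered as the positive class", {
  cc <- confusion(rep(c("disordered", "ordered"), c(5, 5)),
                  rep(c("disordered", "ordered"), c(5, 5)))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  truth <- rep(c("disordered", "ordered"), c(3, 7))
  cc <- confusion(rep("ordered", 10), truth)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 0L, TN = 7L, FP = 0L, FN = 3L))
  # inverting predictions swaps TP<->FN and TN<->FP
  pred <- rep(c("disordered", "ordered"), 5)
  cc1 <- confusion(pred, truth)
  cc2 <- confusion(ifelse(pred == "disordered", "ordered", "disordered"),
                   truth)
  expect_equal(cc2$TP, cc1$FN); expect_equal(cc2$FN, cc1$TP)
  expect_equal(cc2$TN, cc1$FP); expect_equal(cc2$FP, cc1$TN)
  expect_error(confusion("disordered", c("ordered", "ordered")), "mismatch")
  expect_error(confusion(character(0), character(0)), "empty")
})

test_that("metric formulas match hand computation and undefined policy", {
  m <- ch_metrics(list(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$balanced_acc, 0.85)
  expect_equal(m$ppv, 8 / 9)
  expect_equal(m$npv, 9 / 11)
  expect_equal(m$f, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(m$mcc, (8 * 9 - 1 * 2) / sqrt(9 * 10 * 10 * 11))
  expect_equal(m$acc, 17 / 20)

  perfect <- ch_metrics(list(TP = 4, TN = 11, FP = 0, FN = 0))
  for (k in c("acc", "sensitivity", "specificity", "balanced_acc", "ppv",
              "npv", "f", "mcc"))
    expect_equal(perfect[[k]], 1)

  degen <- ch_metrics(list(TP = 0, FP = 0, TN = 5, FN = 3))
  expect_true(is.na(degen$ppv))
  expect_true(is.na(degen$f))
  expect_true(is.na(degen$mcc))
  expect_equal(degen$specificity, 1)
  expect_error(ch_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")
})

test_that("metrics agree with the formula oracle on random confusion matrices", {
  set.seed(1)
  for (i in 1:200) {
    cc <- as.list(sample(0:12, 4, replace = TRUE))
    names(cc) <- c("TP", "TN", "FP", "FN")
    if (sum(unlist(cc)) == 0) next
    got <- ch_metrics(cc)
    want <- oracle_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    for (k in names(want)) expect_equal(got[[k]], want[[k]], info = k)
    if (!is.na(got$balanced_acc))
      expect_equal(got$balanced_acc, (got$sensitivity + got$specificity) / 2)
    if (!is.na(got$f) && !is.na(got$ppv) && got$ppv == got$sensitivity)
      expect_equal(got$f, got$ppv)
  }
})

test_that("MCC is antisymmetric under prediction inversion", {
  set.seed(3)
  for (i in 1:50) {
    cc <- as.list(sample(1:12, 4, replace = TRUE))
    names(cc) <- c("TP", "TN", "FP", "FN")
    inv <- list(TP = cc$FN, FN = cc$TP, TN = cc$FP, FP = cc$TN)
    expect_equal(ch_metrics(inv)$mcc, -ch_metrics(cc)$mcc)
  }
})

test_that("rank-sum AUC equals pair counting and is transform-invariant", {
  lab <- rep(c("disordered", "ordered"), c(4, 6))
  expect_equal(roc_auc(c(5, 6, 7, 8, 1, 2, 3, 4, 4.5, 0), lab), 1)
  expect_equal(roc_auc(rep(2, 10), lab), 0.5)
  set.seed(10)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    labels <- sample(c("disordered", "ordered"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # coarse rounding injects ties
    a <- roc_auc(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(roc_auc(exp(2 * scores), labels), a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("ordered", 3)), "both classes")
})

test_that("F-optimal threshold matches exhaustive search and tie policy", {
  thr <- optimize_threshold_for_f(c(0.1, 0.2, 0.8, 0.9),
                                  c("ordered", "ordered",
                                    "disordered", "disordered"))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "f"), 1)
  set.seed(21)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    labels <- sample(c("disordered", "ordered"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)
    thr <- optimize_threshold_for_f(scores, labels)
    expect_equal(attr(thr, "f"), oracle_best_f(scores, labels),
                 tolerance = 1e-12)
    # the returned threshold actually achieves the reported F
    pred <- ifelse(scores > as.numeric(thr), "disordered", "ordered")
    expect_equal(ch_metrics(confusion(pred, labels))$f, attr(thr, "f"))
  }
  expect_error(optimize_threshold_for_f(1:3, rep("disordered", 3)),
               "both classes")
})

test_that("metrics JSON renders undefined metrics as null", {
  js <- metrics_json(ch_metrics(list(TP = 0, FP = 0, TN = 5, FN = 3)))
  parsed <- jsonlite::fromJSON(js)
  expect_null(parsed$ppv)
  expect_equal(parsed$spec, 1)
})
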