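random_confusion <- function() {
  c <- confusion(runif(40), sample(c(0L, 1L), 40, TRUE,
                                   prob = c(0.6, 0.4)), runif(1))
  c
}

test_that("confusion counts follow the >= threshold convention", {
  c1 <- confusion(c(0.9, 0.1), c(1L, 0L), 0.5)
  expect_equal(c(c1$TP, c1$TN, c1$FP, c1$FN), c(1L, 1L, 0L, 0L))
  # threshold 0: everything predicted positive (ties count as positive)
  c2 <- confusion(c(0.9, 0.1, 0), c(1L, 0L, 0L), 0)
  expect_equal(c2$FP, 2L)
  expect_equal(c2$TN, 0L)
  # hand tally on a 10-item list
  scores <- c(0.95, 0.80, 0.70, 0.65, 0.55, 0.50, 0.40, 0.30, 0.20, 0.10)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  c3 <- confusion(scores, labels, 0.5)
  expect_equal(c(c3$TP, c3$FP, c3$FN, c3$TN), c(4L, 2L, 1L, 3L))
  expect_error(confusion(numeric(0), integer(0), 0.5), "empty")
})

test_that("both metric formulations agree to 1e-12 on random tables", {
  set.seed(61)
  for (i in 1:1000) {
    cts <- confusion(runif(30), sample(c(0L, 1L), 30, TRUE), runif(1))
    if (cts$N_pos == 0 || cts$N_neg == 0) next
    # recompute both published formulations directly and compare
    a <- with(cts, c(Sn = TP / (TP + FN), Sp = TN / (TN + FP),
                     Acc = (TP + TN) / (TP + TN + FP + FN)))
    b <- with(cts, c(Sn = 1 - N_pos_as_neg / N_pos,
                     Sp = 1 - N_neg_as_pos / N_neg,
                     Acc = 1 - (N_pos_as_neg + N_neg_as_pos) / (N_pos + N_neg)))
    expect_lt(max(abs(a - b)), 1e-12)
    m <- metrics(cts)  # internal cross-check also asserts MCC equality
    expect_true(m$Sn >= 0 && m$Sn <= 1)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("the published special cases of the intuitive metrics hold", {
  # no positive misclassified: Sn = 1
  m1 <- metrics(confusion(c(1, 1, 0.2, 0.8), c(1, 1, 0, 0), 0.5))
  expect_equal(m1$Sn, 1)
  # N-+ = N+/2 and N+- = N-/2: MCC = 0
  m2 <- metrics(confusion(c(0.9, 0.1, 0.9, 0.1), c(1, 1, 0, 0), 0.5))
  expect_equal(m2$MCC, 0)
  expect_equal(m2$Acc, 0.5)
  # total misclassification (N-+ = N+, N+- = N-): Acc = 0, MCC = -1
  m3 <- metrics(confusion(c(0.1, 0.1, 0.9, 0.9), c(1, 1, 0, 0), 0.5))
  expect_equal(m3$Acc, 0)
  expect_equal(m3$MCC, -1)
  # vanishing marginal: MCC reported as 0 and flagged
  m4 <- metrics(confusion(c(0.9, 0.9, 0.9), c(1, 1, 0), 0.5))
  expect_false(m4$mcc_defined)
  expect_equal(m4$MCC, 0)
})

test_that("AUC matches the Mann-Whitney formulation and a reference oracle", {
  # perfectly ordered scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # 20-point hand set with ties
  set.seed(62)
  scores <- round(runif(20), 1)
  labels <- sample(c(0L, 1L), 20, TRUE)
  u_auc <- {
    r <- rank(scores)
    np <- sum(labels == 1); nn <- sum(labels == 0)
    (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  expect_equal(roc_auc(scores, labels)$auc, u_auc, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC of independent scores is near 0.5 and transform-invariant", {
  set.seed(63)
  scores <- runif(2000)
  labels <- sample(c(0L, 1L), 2000, TRUE)
  a <- roc_auc(scores, labels)$auc
  expect_gt(a, 0.47); expect_lt(a, 0.53)
  # strictly monotone transforms leave the AUC unchanged
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels)$auc, a, tolerance = 1e-12)
})

test_that("specificity thresholding admits the right number of negatives", {
  neg <- c(0.1, 0.2, 0.9)
  t1 <- threshold_at_specificity(neg, 1.0)
  expect_gt(t1, 0.9)
  expect_equal(sum(neg >= t1), 0L)
  t2 <- threshold_at_specificity(neg, 2 / 3)
  expect_equal(sum(neg >= t2), 1L)
  t3 <- threshold_at_specificity(rep(0.4, 5), 1.0)
  expect_gt(t3, 0.4)
  # achieved specificity always reaches the target on the defining set
  set.seed(64)
  for (i in 1:50) {
    ns <- runif(sample(5:60, 1))
    tgt <- runif(1, 0.05, 1)
    t <- threshold_at_specificity(ns, tgt)
    expect_gte(mean(ns < t), tgt)
  }
})

test_that("evaluate_scores combines confusion metrics with AUC", {
  set.seed(65)
  scores <- c(runif(50, 0.4, 1), runif(50, 0, 0.6))
  labels <- rep(c(1L, 0L), each = 50)
  rep <- evaluate_scores(scores, labels)
  expect_gt(rep$AUC, 0.7)
  f <- tempfile()
  write_metrics(rep, f)
  tab <- read.delim(f)
  expect_equal(tab$metric, c("Sn", "Sp", "Acc", "MCC", "AUC"))
})
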