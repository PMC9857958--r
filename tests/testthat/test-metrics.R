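test_that("the published Semi-SP row is reproduced from its recovered counts", {
  cm <- matrix(c(197L, 20L, 7L, 125L), 2, 2,
               dimnames = list(truth = c("HCC", "MF-ICC"),
                               predicted = c("HCC", "MF-ICC")))
  rep <- metrics_from_confusion(cm)
  expect_equal(round(rep$accuracy, 4), 0.9226)
  expect_equal(round(rep$per_class$precision, 4), c(0.9078, 0.9470))
  expect_equal(round(rep$per_class$recall, 4), c(0.9657, 0.8621))
  expect_equal(round(rep$per_class$f1, 4), c(0.9359, 0.9025))
  expect_equal(rep$n, 349)
})

test_that("recover_confusion finds the unique smallest matrix behind the row", {
  cm <- recover_confusion(table1_semi_sp)
  expect_identical(unname(unclass(cm)),
                   matrix(c(197L, 20L, 7L, 125L), 2, 2))
})

test_that("perfect and degenerate predictors hit the boundary conventions", {
  truth <- rep(c("HCC", "MF-ICC"), each = 10)
  perf <- metrics_report(truth, truth)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$per_class$precision, c(1, 1))
  expect_equal(perf$per_class$recall, c(1, 1))
  expect_equal(perf$per_class$f1, c(1, 1))
  expect_equal(sum(perf$confusion) - sum(diag(perf$confusion)), 0)

  expect_warning(allh <- metrics_report(truth, rep("HCC", 20)),
                 "precision undefined")
  expect_equal(allh$accuracy, 0.5)
  expect_equal(allh$per_class$precision[2], 0)
  expect_equal(allh$per_class$recall[2], 0)
})

test_that("F1 equals 2PR/(P+R) and accuracy equals trace/total exactly", {
  set.seed(21)
  for (i in 1:20) {
    cm <- matrix(sample(0:40, 4, replace = TRUE), 2, 2)
    if (sum(cm) == 0) next
    rep <- suppressWarnings(metrics_from_confusion(cm))
    expect_equal(rep$accuracy, sum(diag(cm)) / sum(cm))
    for (k in 1:2) {
      p <- rep$per_class$precision[k]; r <- rep$per_class$recall[k]
      if (p + r > 0)
        expect_lt(abs(rep$per_class$f1[k] - 2 * p * r / (p + r)), 1e-12)
    }
  }
})

test_that("metrics are invariant to test-set order", {
  set.seed(31)
  truth <- sample(c("HCC", "MF-ICC"), 60, replace = TRUE)
  pred <- sample(c("HCC", "MF-ICC"), 60, replace = TRUE)
  scores <- cbind(runif(60), runif(60))
  scores <- scores / rowSums(scores)
  a <- metrics_report(truth, pred, scores)
  o <- sample(60)
  b <- metrics_report(truth[o], pred[o], scores[o, ])
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$per_class, b$per_class)
  expect_equal(a$auc, b$auc)
  expect_equal(a$confusion, b$confusion)
})

test_that("ROC sweep hits the analytic anchors", {
  sep <- c(0.1, 0.2, 0.8, 0.9)
  lab <- c("HCC", "HCC", "MF-ICC", "MF-ICC")
  expect_equal(roc_auc(sep, lab)$auc, 1.0)
  expect_equal(roc_auc(sep, rev(lab))$auc, 0.0)
  got <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("HCC", "HCC", "MF-ICC", "MF-ICC"))
  expect_equal(got$auc, 0.75)  # 3 concordant of 4 pairs
  expect_error(roc_auc(sep, rep("HCC", 4)), "both classes")
})

test_that("AUC equals the pairwise-concordance oracle up to n = 50", {
  set.seed(41)
  for (i in 1:12) {
    n <- sample(4:50, 1)
    lab <- c("HCC", "MF-ICC", sample(c("HCC", "MF-ICC"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # coarse grid: ties occur
    expect_equal(roc_auc(scores, lab)$auc, oracle_auc(scores, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  lab <- sample(c("HCC", "MF-ICC"), 40, replace = TRUE, prob = c(0.6, 0.4))
  lab[1:2] <- c("HCC", "MF-ICC")
  scores <- runif(40)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = scores, levels = c("HCC", "MF-ICC"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, lab)$auc, ref, tolerance = 1e-12)
})

test_that("macro AUC averages the two per-class AUCs (equal in binary case)", {
  set.seed(61)
  truth <- sample(c("HCC", "MF-ICC"), 30, replace = TRUE)
  truth[1:2] <- c("HCC", "MF-ICC")
  p_mficc <- runif(30)
  scores <- cbind("HCC" = 1 - p_mficc, "MF-ICC" = p_mficc)
  pred <- ifelse(p_mficc > 0.5, "MF-ICC", "HCC")
  rep <- metrics_report(truth, pred, scores)
  expect_equal(unname(rep$auc_per_class["HCC"]),
               unname(rep$auc_per_class["MF-ICC"]))
  expect_equal(rep$auc, mean(rep$auc_per_class))
})

test_that("single-class evaluation reports NaN AUC with a warning", {
  truth <- rep("HCC", 6)
  pred <- c(rep("HCC", 5), "MF-ICC")
  w <- capture_warnings(rep <- metrics_report(truth, pred,
                                              cbind(runif(6), runif(6))))
  expect_true(any(grepl("single-class", w)))
  expect_true(is.nan(rep$auc))
})

test_that("the 2-D embedding is deterministic and separates distant blobs", {
  set.seed(71)
  a <- matrix(rnorm(20 * 6), 20, 6)
  b <- matrix(rnorm(20 * 6, mean = 8), 20, 6)
  feats <- rbind(a, b)
  emb <- embed_2d(feats, seed = 1)
  expect_equal(dim(emb), c(40L, 2L))
  expect_identical(emb, embed_2d(feats, seed = 1))
  # silhouette-style check: between-class distance dwarfs within-class
  lab <- rep(1:2, each = 20)
  centers <- rbind(colMeans(emb[lab == 1, ]), colMeans(emb[lab == 2, ]))
  within <- mean(sqrt(rowSums((emb - centers[lab, ])^2)))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  expect_gt(between, within)  # positive silhouette
  expect_error(embed_2d(matrix(0, 4, 3)), "at least 5")
})
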