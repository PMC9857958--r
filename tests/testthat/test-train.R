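make_lesion_table <- function(n_mficc, n_hcc) {
  data.frame(
    lesion_id = sprintf("L%03d", seq_len(n_mficc + n_hcc)),
    class_label = rep(c("MF-ICC", "HCC"), c(n_mficc, n_hcc)),
    stringsAsFactors = FALSE)
}

test_that("splits conserve the class totals of the published cohort shape", {
  tab <- make_lesion_table(47, 69)
  sp <- split_lesions(tab, c(0.6, 0.2, 0.2), seed = 7)
  counts <- table(sp$class_label, sp$split)
  expect_equal(sum(counts["MF-ICC", ]), 47)
  expect_equal(sum(counts["HCC", ]), 69)
  # largest-remainder allocation stays within one lesion of the exact ratios
  for (cls in rownames(counts)) {
    n <- sum(counts[cls, ])
    expect_true(all(abs(counts[cls, c("train", "validation", "test")] -
                          c(0.6, 0.2, 0.2) * n) < 1))
  }
  expect_setequal(sp$lesion_id, tab$lesion_id)
})

test_that("degenerate ratios, determinism and small-cohort errors", {
  tab <- make_lesion_table(5, 6)
  all_train <- split_lesions(tab, c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  a <- split_lesions(tab, seed = 3)
  b <- split_lesions(tab, seed = 3)
  expect_identical(a, b)
  c2 <- split_lesions(tab, seed = 4)
  expect_false(identical(a$split[order(a$lesion_id)],
                         c2$split[order(c2$lesion_id)]))
  expect_error(split_lesions(make_lesion_table(2, 6)), "at least 3")
})

test_that("no lesion ever spans two splits", {
  tab <- make_lesion_table(9, 12)
  slices <- tab[rep(seq_len(nrow(tab)), each = 4), ]
  for (seed in 1:20) {
    sp <- split_lesions(slices, seed = seed)
    expect_equal(nrow(sp), nrow(tab))  # one assignment per lesion
    expect_true(all(table(sp$lesion_id) == 1))
  }
})

test_that("the learning-rate schedule decays by 0.1 every 30 epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(29, cfg), 0.001)
  expect_equal(lr_at_epoch(30, cfg), 0.0001)
  expect_equal(lr_at_epoch(95, cfg), 1e-6)  # floor(95/30) = 3 decays
  expect_error(lr_at_epoch(-1, cfg), "non-negative")
})

test_that("training is deterministic and reduces the loss", {
  set.seed(1)
  x <- array(round(runif(224 * 224 * 8) * 256) / 256, c(224, 224, 1, 8))
  y <- rep(c("HCC", "MF-ICC"), 4)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 5)
  m1 <- sffnet_model(sffnet_config("reduced"), seed = 2)
  f1 <- train_sffnet(m1, x, y, x, y, cfg)
  m2 <- sffnet_model(sffnet_config("reduced"), seed = 2)
  f2 <- train_sffnet(m2, x, y, x, y, cfg)
  expect_identical(f1$history, f2$history)
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_identical(sffnet_forward(m1, x[, , , 1, drop = FALSE])$logits,
                   sffnet_forward(m2, x[, , , 1, drop = FALSE])$logits)
  expect_error(train_sffnet(m1, x[, , , 0, drop = FALSE], character(0),
                            x, y, cfg), "empty")
})

test_that("a reduced model memorizes a small synthetic patch set", {
  co <- make_cohort(4, phantom_spec(), seed = 2, slices_per_lesion = 4)
  patches <- preprocess_cohort(co, "semi_sp")
  lab <- co$manifest$class_label
  m <- sffnet_model(sffnet_config("reduced"), seed = 1)
  cfg <- train_config(epochs = 14, batch_size = 8, seed = 9)
  fit <- train_sffnet(m, patches, lab, patches, lab, cfg)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_gte(max(fit$history$val_accuracy), 0.95)  # memorization
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # best checkpoint = highest validation accuracy, earliest on ties
  best <- fit$history$epoch[which.max(fit$history$val_accuracy)]
  expect_equal(fit$best_epoch, best)
})

test_that("evaluation refuses augmented test patches", {
  ts <- toy_slice()
  p <- apply_strategy(ts$slice, ts$mask, "semi_sp")
  p$provenance$augmented <- TRUE
  m <- sffnet_model(sffnet_config("reduced"), seed = 1)
  expect_error(evaluate_model(m, list(p), "HCC"), "augmented")
})

test_that("lesion-level majority vote aggregates per-slice predictions", {
  pred <- c("HCC", "HCC", "MF-ICC", "MF-ICC", "MF-ICC", "HCC")
  lesions <- c("L1", "L1", "L1", "L2", "L2", "L2")
  truth <- c(rep("HCC", 3), rep("MF-ICC", 3))
  rep <- lesion_vote_report(pred, lesions, truth)
  expect_equal(rep$n, 2)
  expect_equal(rep$accuracy, 1)
})
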