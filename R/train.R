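# Lesion-grouped splitting and the training protocol: SGD with momentum on
# 2-class cross-entropy, initial learning rate 1e-3 decayed by 0.1 every 30
# epochs, batch size 16; the checkpoint with the best validation accuracy
# (earliest epoch on ties) is kept. Splitting is stratified by class at the
# lesion level so that no lesion contributes slices to two partitions.

#' Training protocol configuration
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied every
#'   `lr_step_epochs`.
#' @param lr_step_epochs Epoch period of the decay.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs.
#' @param momentum SGD momentum (the protocol names plain SGD; momentum 0.9
#'   is the conventional default and is declared here rather than hidden).
#' @param weight_decay L2 penalty, default 0.
#' @param seed Shuffling seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.001, lr_decay_factor = 0.1,
                         lr_step_epochs = 30L, batch_size = 16L,
                         epochs = 100L, momentum = 0.9, weight_decay = 0,
                         seed = 0L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_step_epochs >= 1,
            batch_size >= 1, epochs >= 1, momentum >= 0, weight_decay >= 0)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `initial_lr * lr_decay_factor ^ floor(epoch / lr_step_epochs)` with
#' 0-based epochs.
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
lr_at_epoch <- function(epoch, config = train_config()) {
  if (any(epoch < 0)) stopf("epoch must be non-negative")
  config$initial_lr * config$lr_decay_factor ^ (epoch %/% config$lr_step_epochs)
}

#' Stratified lesion-level train/validation/test split
#'
#' Lesions (not slices) are assigned to partitions so every slice of a
#' lesion inherits its lesion's split. Within each class the partition
#' sizes follow the ratios by largest-remainder allocation; the draw is
#' deterministic in `seed`.
#'
#' @param lesion_table Data frame with columns `lesion_id` and
#'   `class_label` (one row per lesion; duplicated lesion ids are
#'   tolerated and collapsed).
#' @param ratios `c(train, validation, test)`, summing to 1.
#' @param seed Split seed.
#' @return Data frame with `lesion_id`, `class_label`, `split`; attributes
#'   `ratios` and `seed`.
#' @export
split_lesions <- function(lesion_table, ratios = c(0.6, 0.2, 0.2), seed = 0L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-8)
  tab <- unique(lesion_table[, c("lesion_id", "class_label")])
  if (any(table(tab$lesion_id) > 1))
    stopf("a lesion_id appears with two different class labels")
  counts <- table(tab$class_label)
  if (any(counts < 3))
    stopf("need at least 3 lesions per class; got %s",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  parts <- c("train", "validation", "test")
  out <- lapply(split(tab, tab$class_label), function(g) {
    n <- nrow(g)
    exact <- ratios * n
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, seq_along(ratios), decreasing = c(TRUE, FALSE),
                     method = "radix")[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    ids <- local_seed(mix_seed(seed, g$class_label[1]), sample(g$lesion_id))
    g2 <- data.frame(lesion_id = ids,
                     class_label = g$class_label[1],
                     split = rep(parts, times = base),
                     stringsAsFactors = FALSE)
    g2
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ratios") <- ratios
  attr(res, "seed") <- seed
  res
}

# Encode class labels as 0-based integers in .classes order.
encode_labels <- function(labels) {
  y <- match(as.character(labels), .classes) - 1L
  if (anyNA(y)) stopf("labels outside the class set %s",
                      paste(.classes, collapse = "/"))
  y
}

#' Train an SFFNet model
#'
#' Runs the SGD protocol of [train_config()], logging the per-epoch training
#' loss and validation accuracy, and restores the weights of the epoch with
#' the highest validation accuracy (earliest on ties) before returning.
#'
#' @param model An `sffnet_model` (modified in place).
#' @param train_x `(H,W,C,N)` array or list of patches.
#' @param train_y,val_y Class labels.
#' @param val_x Validation inputs in the same form.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `history` (data frame epoch/lr/train_loss/
#'   val_accuracy), `best_epoch`, `best_val_accuracy`.
#' @export
train_sffnet <- function(model, train_x, train_y, val_x, val_y,
                         config = train_config(), verbose = FALSE) {
  if (is.list(train_x)) train_x <- patches_to_batch(train_x)
  if (is.list(val_x)) val_x <- patches_to_batch(val_x)
  n <- dim(train_x)[4]
  if (n == 0 || length(train_y) != n) stopf("empty or mismatched training set")
  if (dim(val_x)[4] == 0) stopf("empty validation set")
  ytr <- encode_labels(train_y)
  yva <- as.character(val_y)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_accuracy = numeric())
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_w <- NULL
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, config)
    ord <- local_seed(mix_seed(config$seed, 1000L + epoch), sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      loss <- sff_train_batch(model$ptr,
                              train_x[, , , idx, drop = FALSE],
                              ytr[idx], lr, config$momentum,
                              config$weight_decay)
      losses <- c(losses, loss)
    }
    if (!all(is.finite(losses))) stopf("non-finite loss at epoch %d", epoch)
    probs <- predict_proba(model, val_x, config$batch_size)
    pred <- .classes[max.col(probs, ties.method = "first")]
    acc <- mean(pred == yva)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = mean(losses),
                                         val_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_epoch <- epoch
      best_w <- sff_get_weights(model$ptr)
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val acc %.4f",
                      epoch, lr, mean(losses), acc))
  }
  sff_set_weights(model$ptr, best_w)
  list(history = history, best_epoch = best_epoch,
       best_val_accuracy = best_acc)
}

#' Evaluate a model on held-out patches
#'
#' Predictions are the argmax of the logits; AUC scores are the softmax
#' probabilities with each class treated as positive in turn (macro
#' averaged overall).
#'
#' @param model An `sffnet_model`.
#' @param x Test inputs (`(H,W,C,N)` array or list of patches); test
#'   patches must never be augmented.
#' @param labels True class labels.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, x, labels) {
  if (is.list(x)) {
    aug <- vapply(x, function(p) isTRUE(p$provenance$augmented), logical(1))
    if (any(aug)) stopf("test patches must not be augmented")
    x <- patches_to_batch(x)
  }
  probs <- predict_proba(model, x)
  pred <- .classes[max.col(probs, ties.method = "first")]
  metrics_report(labels, pred, scores = probs)
}

#' Lesion-level majority-vote report
#'
#' Aggregates per-slice predictions to one prediction per lesion by
#' majority vote (ties broken toward the first class) and reports the
#' lesion-level confusion and rates. Clearly separated from the per-slice
#' metrics, which are the primary output.
#'
#' @param predicted Per-slice predicted labels.
#' @param lesion_ids Per-slice lesion identifiers.
#' @param truth Per-slice true labels (constant within lesion).
#' @return A `metrics_report` at lesion level.
#' @export
lesion_vote_report <- function(predicted, lesion_ids, truth) {
  agg <- function(v) .classes[which.max(tabulate(match(v, .classes),
                                                 nbins = length(.classes)))]
  pl <- tapply(as.character(predicted), lesion_ids, agg)
  tl <- tapply(as.character(truth), lesion_ids, function(v) v[1])
  metrics_report(as.character(tl), as.character(pl[names(tl)]))
}
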