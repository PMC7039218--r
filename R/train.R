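# Training policy, per-class 60/10/30 splitting, the Adam training loop and
# evaluation metrics.

#' Training policy
#'
#' Defaults mirror the reference protocol: Adam, initial learning rate 0.01
#' shrunk 10-fold at epochs 20 and 40, 50 epochs, batches of 128, classic L2
#' weight penalty (1e-2 for Myo-style runs; 1e-3 is the DB5-style setting).
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied at each milestone.
#' @param milestones Epochs (1-based) at which the decay applies.
#' @param epochs Total training epochs.
#' @param batch_size Samples per optimizer step.
#' @param weight_decay Classic L2 coefficient (gradient gains
#'   `weight_decay * w`).
#' @param seed Seed for shuffling and any stochastic layer.
#' @return Object of class `train_policy`.
#' @export
train_policy <- function(initial_lr = 0.01, lr_decay_factor = 0.1,
                         milestones = c(20L, 40L), epochs = 50L,
                         batch_size = 128L, weight_decay = 1e-2,
                         seed = 1L) {
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  if (any(milestones < 1L) || any(milestones > epochs))
    abort_invalid("milestones must lie within [1, epochs]")
  if (initial_lr <= 0) abort_invalid("`initial_lr` must be positive")
  if (weight_decay < 0) abort_invalid("`weight_decay` must be >= 0")
  structure(list(optimizer = "adam", initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 milestones = sort(as.integer(milestones)),
                 epochs = epochs, batch_size = batch_size,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_policy")
}

#' Learning rate at a given epoch
#'
#' Step schedule: the decay applies *at* each milestone epoch, so with the
#' defaults epochs 1-19 run at 0.01, 20-39 at 0.001, and 40 onwards at 0.0001.
#'
#' @param policy A [train_policy()].
#' @param epoch 1-based epoch within `[1, policy$epochs]`.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(policy, epoch) {
  if (!inherits(policy, "train_policy"))
    abort_invalid("`policy` must be a train_policy")
  if (!is_count(epoch) || epoch > policy$epochs)
    abort_invalid("epoch %s outside [1, %d]", format(epoch), policy$epochs)
  policy$initial_lr * policy$lr_decay_factor^sum(epoch >= policy$milestones)
}

#' Per-class shuffled train/validation/test split
#'
#' Within each class the sample indices are shuffled with the seeded RNG and
#' partitioned 60/10/30 (by default): the first `floor(n * 0.6)` go to train,
#' the next `floor(n * 0.1)` to validation, and the remainder — "the last
#' 30%" — to test.
#'
#' @param labels Factor (or coercible) of per-sample class labels.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return Object of class `dataset_split`: list with integer index vectors
#'   `train`, `val`, `test`, plus `per_class` bookkeeping and the inputs.
#' @export
split_dataset <- function(labels, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  labels <- as.factor(labels)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0))
    abort_invalid("`fractions` must be three non-negative values summing to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tr <- va <- te <- integer(0)
  per_class <- list()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 3L)
      abort_invalid("class '%s' has only %d samples; need at least 3",
                    cl, length(idx))
    idx <- idx[sample.int(length(idx))]
    n_tr <- floor(length(idx) * fractions[1])
    n_va <- floor(length(idx) * fractions[2])
    per_class[[cl]] <- list(train = idx[seq_len(n_tr)],
                            val = idx[n_tr + seq_len(n_va)],
                            test = idx[(n_tr + n_va + 1L):length(idx)])
    tr <- c(tr, per_class[[cl]]$train)
    va <- c(va, per_class[[cl]]$val)
    te <- c(te, per_class[[cl]]$test)
  }
  structure(list(train = tr, val = va, test = te, per_class = per_class,
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Train an EMGNet model
#'
#' Adam on softmax cross-entropy (the one-hot loss) with a classic L2 weight
#' penalty folded into the gradient, a fixed epoch count, per-epoch
#' reshuffling (last short batch kept), and the step learning-rate schedule of
#' [lr_at_epoch()].  Fully deterministic given `policy$seed`.  The validation
#' split is monitored but never steers training (no early stopping).
#'
#' @param model An `emgnet_model` (freshly built, see [build_emgnet()]).
#' @param dataset An `emg_tensor_dataset`.
#' @param split A [split_dataset()] result over the dataset's samples.
#' @param policy A [train_policy()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained), `history` (data.frame per epoch:
#'   train/val loss and accuracy, lr), and `classes`.
#' @export
train_emgnet <- function(model, dataset, split, policy = train_policy(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "emgnet_model"),
            inherits(dataset, "emg_tensor_dataset"),
            inherits(split, "dataset_split"),
            inherits(policy, "train_policy"))
  if (length(split$train) == 0L) abort_invalid("empty training set")
  classes <- levels(dataset$labels)
  if (length(classes) != model$config$n_classes)
    abort_invalid("model has %d classes but dataset has %d",
                  model$config$n_classes, length(classes))
  y_all <- as.integer(dataset$labels)
  x_all <- dataset$tensors
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(policy$seed)
  params <- model$params
  state <- adam_init(params)
  t_step <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), train_acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  decayed <- c("wh", paste0("w", 1:4), if (model$config$use_bias)
    paste0("b", 1:4), if (model$config$head_bias) "bh")
  for (epoch in seq_len(policy$epochs)) {
    lr <- lr_at_epoch(policy, epoch)
    order_idx <- split$train[sample.int(length(split$train))]
    n_steps <- ceiling(length(order_idx) / policy$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (s in seq_len(n_steps)) {
      lo <- (s - 1L) * policy$batch_size + 1L
      hi <- min(s * policy$batch_size, length(order_idx))
      bidx <- order_idx[lo:hi]
      xb <- x_all[, , , bidx, drop = FALSE]
      yb <- y_all[bidx]
      model$params <- params
      fw <- emgnet_forward_full(model, xb, train = TRUE)
      lo_ce <- softmax_ce_loss(fw$logits, yb)
      grads <- emgnet_backward(model, fw, lo_ce$dlogits)
      if (policy$weight_decay > 0)
        for (nm in decayed)
          grads[[nm]] <- grads[[nm]] + policy$weight_decay * params[[nm]]
      t_step <- t_step + 1L
      up <- adam_step(params, grads, state, lr, t_step)
      params <- up$params
      state <- up$state
      ep_loss <- ep_loss + lo_ce$loss * length(bidx)
      pred <- max.col(t(lo_ce$probs), ties.method = "first")
      ep_correct <- ep_correct + sum(pred == yb)
    }
    model$params <- params
    val <- if (length(split$val) > 0)
      eval_loss_acc(model, x_all, y_all, split$val)
    else list(loss = NA_real_, acc = NA_real_)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / length(order_idx),
      train_acc = 100 * ep_correct / length(order_idx),
      val_loss = val$loss, val_acc = val$acc))
    if (verbose)
      message(sprintf("epoch %02d lr %.4g train loss %.4f acc %.2f%% val acc %.2f%%",
                      epoch, lr, hist$train_loss[epoch],
                      hist$train_acc[epoch], val$acc))
  }
  model$params <- params
  list(model = model, history = hist, classes = classes,
       total_steps = t_step)
}

# Loss/accuracy on an index subset, batched to bound memory.
eval_loss_acc <- function(model, x_all, y_all, idx, batch = 256L) {
  loss <- 0; correct <- 0L
  for (lo in seq(1L, length(idx), by = batch)) {
    hi <- min(lo + batch - 1L, length(idx))
    bidx <- idx[lo:hi]
    fw <- emgnet_forward_full(model, x_all[, , , bidx, drop = FALSE])
    ce <- softmax_ce_loss(fw$logits, y_all[bidx])
    loss <- loss + ce$loss * length(bidx)
    pred <- max.col(t(ce$probs), ties.method = "first")
    correct <- correct + sum(pred == y_all[bidx])
  }
  list(loss = loss / length(idx), acc = 100 * correct / length(idx))
}

#' Predict gesture labels for tensors
#'
#' @param trained Result of [train_emgnet()] (or an `emgnet_model` plus
#'   explicit `classes`).
#' @param dataset An `emg_tensor_dataset` or tensor array.
#' @param idx Optional subset of sample indices.
#' @return Factor of predicted labels.
#' @export
predict_emgnet <- function(trained, dataset, idx = NULL) {
  model <- if (inherits(trained, "emgnet_model")) trained else trained$model
  classes <- if (inherits(trained, "emgnet_model")) NULL else trained$classes
  x <- if (inherits(dataset, "emg_tensor_dataset")) dataset$tensors
       else dataset
  if (!is.null(idx)) x <- x[, , , idx, drop = FALSE]
  logits <- forward_emgnet(model, x)
  pred <- max.col(logits, ties.method = "first")
  if (is.null(classes)) pred else factor(classes[pred], levels = classes)
}

#' Evaluate predictions on a test set
#'
#' @param predicted Factor/character of predicted labels.
#' @param truth Factor/character of true labels (same length, non-empty).
#' @return Object of class `emg_metrics`: list with `accuracy` (percent),
#'   `per_class` (percent per true class), `confusion` (rows = truth,
#'   columns = predicted), `n`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (length(truth) == 0L) abort_invalid("empty test set")
  if (length(predicted) != length(truth))
    abort_invalid("prediction/truth length mismatch")
  lev <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  confusion <- table(truth = truth, predicted = predicted)
  acc <- 100 * sum(diag(confusion)) / length(truth)
  per_class <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(accuracy = acc, per_class = per_class,
                 confusion = confusion, n = length(truth)),
            class = "emg_metrics")
}

#' Evaluate a trained EMGNet on a split's test set
#'
#' @param trained Result of [train_emgnet()].
#' @param dataset The `emg_tensor_dataset` used for the split.
#' @param split A [split_dataset()] result; its `test` indices are used.
#' @return An `emg_metrics` object.
#' @export
evaluate_emgnet <- function(trained, dataset, split) {
  if (length(split$test) == 0L) abort_invalid("empty test set")
  pred <- predict_emgnet(trained, dataset, split$test)
  evaluate_predictions(pred, dataset$labels[split$test])
}

#' @export
print.emg_metrics <- function(x, ...) {
  cat(sprintf("<emg_metrics> accuracy %.2f%% on %d samples\n", x$accuracy,
              x$n))
  cat("per-class (%):\n")
  print(round(x$per_class, 2))
  invisible(x)
}
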