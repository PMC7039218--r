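# EMGNet: a compact four-layer CNN for 8-channel scalogram tensors.
#
# Structural rules: every kernel is 3 x 3; a layer whose output width exceeds
# its input width uses stride 2 (halving the feature map), otherwise stride 1;
# padding is 1 everywhere; no fully connected layer — the head is adaptive
# mean pooling to 1 x 1 followed by a 1 x 1 convolution to the class logits.
# The default widths (18, 18, 43, 58) were frozen by a constrained integer
# search (scripts/width_search.R) so that the 7-class model has exactly 34311
# learnable parameters.

EMGNET_DEFAULT_WIDTHS <- c(18L, 18L, 43L, 58L)

#' EMGNet architecture configuration
#'
#' @param n_classes Number of gesture classes.
#' @param in_channels Input channels (default 8).
#' @param input_size Spatial size of each channel (default `c(15, 25)`).
#' @param conv_widths Output-channel counts of the four body layers.
#' @param activation `"prelu"` (parametric rectifier, per-channel slopes,
#'   the default) or `"relu"`.
#' @param use_bias Biases on the body convolutions.
#' @param head_bias Bias on the 1 x 1 classifier convolution.
#' @param pool `"mean"` (adaptive mean pooling, default) or `"max"`.
#' @return Object of class `emgnet_config`.
#' @export
emgnet_config <- function(n_classes,
                          in_channels = 8L,
                          input_size = c(15L, 25L),
                          conv_widths = EMGNET_DEFAULT_WIDTHS,
                          activation = c("prelu", "relu"),
                          use_bias = TRUE,
                          head_bias = TRUE,
                          pool = c("mean", "max")) {
  activation <- match.arg(activation)
  pool <- match.arg(pool)
  n_classes <- check_count(n_classes, "n_classes")
  in_channels <- check_count(in_channels, "in_channels")
  if (length(conv_widths) != 4L || any(conv_widths < 1))
    abort_invalid("`conv_widths` must be 4 positive layer widths")
  if (length(input_size) != 2L || any(input_size < 1))
    abort_invalid("`input_size` must be two positive extents")
  cfg <- structure(list(n_classes = n_classes, in_channels = in_channels,
                        input_size = as.integer(input_size),
                        conv_widths = as.integer(conv_widths),
                        activation = activation,
                        use_bias = isTRUE(use_bias),
                        head_bias = isTRUE(head_bias),
                        pool = pool),
                   class = "emgnet_config")
  # stride-rule consistency: the spatial map must survive all four layers
  sz <- cfg$input_size
  for (s in emgnet_strides(cfg)) {
    sz <- c(conv_out_dim(sz[1], stride = s), conv_out_dim(sz[2], stride = s))
    if (any(sz < 1L))
      abort_invalid("conv_widths collapse the %dx%d input below 1x1",
                    input_size[1], input_size[2])
  }
  cfg
}

# Stride per body layer: 2 exactly where the width increases, else 1.
emgnet_strides <- function(config) {
  ins <- c(config$in_channels, config$conv_widths[1:3])
  ifelse(config$conv_widths > ins, 2L, 1L)
}

#' Build an EMGNet model
#'
#' Instantiates the layer graph and its parameters with seeded He fan-in
#' initialization (PReLU slopes start at 0.25, biases at 0).
#'
#' @param config An [emgnet_config()].
#' @param seed RNG seed for the weight initialization.
#' @return Object of class `emgnet_model` with a parameter registry
#'   (`$params`), layer metadata, and the config.
#' @export
build_emgnet <- function(config, seed = 1L) {
  if (!inherits(config, "emgnet_config"))
    abort_invalid("`config` must be an emgnet_config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  strides <- emgnet_strides(config)
  widths <- config$conv_widths
  ins <- c(config$in_channels, widths[1:3])
  params <- list()
  meta <- vector("list", 4L)
  sz <- config$input_size
  for (l in 1:4) {
    fan_in <- 9L * ins[l]
    params[[paste0("w", l)]] <-
      matrix(stats::rnorm(widths[l] * fan_in, sd = sqrt(2 / fan_in)),
             widths[l], fan_in)
    if (config$use_bias) params[[paste0("b", l)]] <- numeric(widths[l])
    if (config$activation == "prelu")
      params[[paste0("a", l)]] <- rep(0.25, widths[l])
    meta[[l]] <- c(list(H = sz[1], W = sz[2], C = ins[l], stride = strides[l]),
                   im2col_indices(sz[1], sz[2], ins[l], stride = strides[l]))
    sz <- c(meta[[l]]$oh, meta[[l]]$ow)
  }
  params$wh <- matrix(stats::rnorm(config$n_classes * widths[4],
                                   sd = sqrt(2 / widths[4])),
                      config$n_classes, widths[4])
  if (config$head_bias) params$bh <- numeric(config$n_classes)
  structure(list(config = config, params = params, layer_meta = meta,
                 final_size = sz, seed = as.integer(seed)),
            class = "emgnet_model")
}

#' Count learnable parameters
#'
#' Sums every learnable scalar in the model's parameter registry: convolution
#' weights, biases, PReLU slopes, and the classifier head.
#'
#' @param model An `emgnet_model`.
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  if (!inherits(model, "emgnet_model"))
    abort_invalid("`model` must be an emgnet_model")
  sum(vapply(model$params, length, 0L))
}

#' @export
print.emgnet_model <- function(x, ...) {
  cfg <- x$config
  strides <- emgnet_strides(cfg)
  cat(sprintf("<emgnet_model> %d-class, input %d x %d x %d\n",
              cfg$n_classes, cfg$in_channels, cfg$input_size[1],
              cfg$input_size[2]))
  ins <- c(cfg$in_channels, cfg$conv_widths[1:3])
  for (l in 1:4)
    cat(sprintf("  conv%d 3x3 %d->%d stride %d + %s\n", l, ins[l],
                cfg$conv_widths[l], strides[l], cfg$activation))
  cat(sprintf("  adaptive %s pool -> 1x1 conv -> %d logits\n", cfg$pool,
              cfg$n_classes))
  cat(sprintf("  parameters: %d\n", count_parameters(x)))
  invisible(x)
}

# Full forward pass.  x: (C, H, W, N) channel-first array.  Returns logits
# (n_classes, N) plus caches for backprop when `train = TRUE`.
emgnet_forward_full <- function(model, x, train = FALSE) {
  cfg <- model$config
  p <- model$params
  N <- dim(x)[4]
  act <- aperm(x, c(2, 3, 1, 4))                     # (H, W, C, N)
  caches <- if (train) vector("list", 4L) else NULL
  for (l in 1:4) {
    mt <- model$layer_meta[[l]]
    cf <- conv_forward(act, p[[paste0("w", l)]],
                       if (cfg$use_bias) p[[paste0("b", l)]] else NULL, mt)
    pre <- cf$out                                    # (F, P*N)
    if (cfg$activation == "prelu") {
      pf <- prelu_forward(pre, p[[paste0("a", l)]])
      post <- pf$out
      if (train) caches[[l]] <- list(xcol = cf$xcol, pre = pre, neg = pf$neg,
                                     meta = mt, N = N)
    } else {
      post <- pmax(pre, 0)
      if (train) caches[[l]] <- list(xcol = cf$xcol, pre = pre, neg = pre < 0,
                                     meta = mt, N = N)
    }
    act <- array(post, c(cfg$conv_widths[l], mt$oh, mt$ow, N))
    act <- aperm(act, c(2, 3, 1, 4))                 # back to (H, W, C, N)
  }
  d <- dim(act)                                      # (oh, ow, C4, N)
  flat <- matrix(act, d[1] * d[2], d[3] * d[4])
  pooled <- if (cfg$pool == "mean") colMeans(flat)
            else apply(flat, 2, max)
  pooledm <- matrix(pooled, d[3], N)                 # (C4, N)
  logits <- p$wh %*% pooledm
  if (cfg$head_bias) logits <- logits + p$bh
  list(logits = logits, pooled = pooledm, caches = caches,
       last_dim = d, last_flat = if (train) flat else NULL)
}

#' Forward pass: batch of tensors to class logits
#'
#' @param model An `emgnet_model`.
#' @param x One tensor (array `in_channels x H x W`), a batch (array
#'   `in_channels x H x W x N`), or an `emg_tensor`/`emg_tensor_dataset`.
#' @return Matrix of logits, one row per sample, one column per class.
#' @export
forward_emgnet <- function(model, x) {
  if (!inherits(model, "emgnet_model"))
    abort_invalid("`model` must be an emgnet_model")
  if (inherits(x, "emg_tensor")) x <- x$tensor
  if (inherits(x, "emg_tensor_dataset")) x <- x$tensors
  cfg <- model$config
  want <- c(cfg$in_channels, cfg$input_size)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L || !all(dim(x)[1:3] == want))
    abort_invalid("input shape (%s) does not match expected (%s x N)",
                  paste(dim(x), collapse = ", "),
                  paste(want, collapse = ", "))
  t(emgnet_forward_full(model, x)$logits)
}

# Backward pass given dlogits (n_classes, N); returns gradient list aligned
# with the parameter registry.
emgnet_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  grads$wh <- tcrossprod(dlogits, fw$pooled)
  if (cfg$head_bias) grads$bh <- rowSums(dlogits)
  dpooled <- crossprod(p$wh, dlogits)                # (C4, N)
  d <- fw$last_dim
  if (cfg$pool == "mean") {
    dflat <- matrix(rep(as.vector(dpooled) / (d[1] * d[2]), each = d[1] * d[2]),
                    d[1] * d[2], d[3] * d[4])
  } else {
    dflat <- matrix(0, d[1] * d[2], d[3] * d[4])
    hit <- max.col(t(fw$last_flat), ties.method = "first")
    dflat[cbind(hit, seq_len(d[3] * d[4]))] <- as.vector(dpooled)
  }
  dact <- array(dflat, d)                            # (oh, ow, C4, N)
  for (l in 4:1) {
    cache <- fw$caches[[l]]
    mt <- cache$meta
    N <- cache$N
    # (oh, ow, F, N) -> (F, P*N)
    dpost <- matrix(aperm(dact, c(3, 1, 2, 4)), cfg$conv_widths[l],
                    mt$pos * N)
    if (cfg$activation == "prelu") {
      pb <- prelu_backward(dpost, cache$pre, p[[paste0("a", l)]], cache$neg,
                           per_channel = TRUE)
      dpre <- pb$dx
      grads[[paste0("a", l)]] <- pb$da
    } else {
      dpre <- dpost
      dpre[cache$neg] <- 0
    }
    cb <- conv_backward(dpre, cache$xcol, p[[paste0("w", l)]], mt,
                        mt$H, mt$W, mt$C, N, cfg$use_bias)
    grads[[paste0("w", l)]] <- cb$dW
    if (cfg$use_bias) grads[[paste0("b", l)]] <- cb$db
    dact <- cb$dx                                    # (H, W, C, N)
  }
  grads
}

#' Cross-entropy of a predicted distribution against a one-hot target
#'
#' `Loss = -sum_i y_i log(y'_i)`, i.e. minus the log-probability assigned to
#' the true class.  Probabilities are clamped at 1e-12 for log safety.
#'
#' @param predicted_probs Probability vector (sums to 1 within 1e-6) or a
#'   matrix with one distribution per row.
#' @param onehot_target One-hot vector (or matrix of rows) of the same shape.
#' @return Scalar loss (vector of per-row losses for matrix input).
#' @export
cross_entropy <- function(predicted_probs, onehot_target) {
  pv <- rbind(predicted_probs)
  yv <- rbind(onehot_target)
  if (!all(dim(pv) == dim(yv)))
    abort_invalid("prediction and target shapes differ")
  if (any(abs(rowSums(pv) - 1) > 1e-6) || any(pv < -1e-9))
    abort_invalid("`predicted_probs` rows must lie on the probability simplex")
  if (any(abs(rowSums(yv) - 1) > 1e-9) || !all(yv %in% c(0, 1)))
    abort_invalid("`onehot_target` must be one-hot")
  loss <- -rowSums(yv * log(pmax(pv, 1e-12)))
  if (is.vector(predicted_probs)) loss[[1]] else unname(loss)
}
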