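# Minimal CNN engine: im2col convolutions on BLAS, PReLU, adaptive pooling,
# softmax cross-entropy and Adam.  Written for small inputs (8 x 15 x 25) and
# bit-exact seed determinism; no external deep-learning framework exists in
# the supported R stack.
#
# Layouts: per-layer activations are kept as (F, P*N) matrices (F = output
# channels, P = spatial positions column-major, N = batch), with the spatial
# dims carried alongside.  Inputs to a conv are arrays (H, W, C, N).

conv_out_dim <- function(n, kernel = 3L, stride = 1L, pad = 1L) {
  floor((n + 2L * pad - kernel) / stride) + 1L
}

# Precompute im2col gather indices for a (H, W, C) input padded by `pad`.
# Returns linear indices into the padded (Hp, Wp, C) volume, ordered
# (di, dj, k) fastest then output position (i fastest, then j).
im2col_indices <- function(H, W, C, kernel = 3L, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oh <- conv_out_dim(H, kernel, stride, pad)
  ow <- conv_out_dim(W, kernel, stride, pad)
  di <- rep(seq_len(kernel), times = kernel)          # rows fastest
  dj <- rep(seq_len(kernel), each = kernel)
  k <- rep(seq_len(C), each = kernel * kernel)
  off <- (rep(di, C) - 1L) + (rep(dj, C) - 1L) * Hp + (k - 1L) * Hp * Wp
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- (stride * (oi - 1L) + 1L) + (stride * (oj - 1L)) * Hp
  idx <- outer(off, base, "+")                        # (k*k*C) x (oh*ow)
  list(idx = as.integer(idx), oh = oh, ow = ow, Hp = Hp, Wp = Wp,
       rows = kernel * kernel * C, pos = oh * ow)
}

pad_input <- function(x, pad) {
  # x: (H, W, C, N) -> (H+2p, W+2p, C, N)
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), , ] <- x
  out
}

conv_forward <- function(x, Wm, b, meta) {
  # x: (H, W, C, N); Wm: (F, 9C); returns list(out = (F, P*N) matrix, xcol)
  d <- dim(x)
  N <- d[4]
  xp <- pad_input(x, (meta$Hp - d[1]) / 2L)
  dim(xp) <- c(meta$Hp * meta$Wp * d[3], N)
  xcol <- xp[meta$idx, , drop = FALSE]                 # (rows*P, N)
  dim(xcol) <- c(meta$rows, meta$pos * N)
  out <- Wm %*% xcol
  if (!is.null(b)) out <- out + b
  list(out = out, xcol = xcol)
}

conv_backward <- function(dout, xcol, Wm, meta, H, W, C, N, use_bias) {
  # dout: (F, P*N)
  dW <- tcrossprod(dout, xcol)                         # (F, rows)
  db <- if (use_bias) rowSums(dout) else NULL
  dxcol <- crossprod(Wm, dout)                         # (rows, P*N)
  dim(dxcol) <- c(meta$rows * meta$pos, N)
  agg <- rowsum(dxcol, group = meta$idx, reorder = FALSE)
  where <- as.integer(rownames(agg))
  dxp <- matrix(0, meta$Hp * meta$Wp * C, N)
  dxp[where, ] <- agg
  dim(dxp) <- c(meta$Hp, meta$Wp, C, N)
  pad <- (meta$Hp - H) / 2L
  dx <- if (pad > 0) dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , ,
                         drop = FALSE]
        else dxp
  dim(dx) <- c(H, W, C, N)
  list(dW = dW, db = db, dx = dx)
}

prelu_forward <- function(x, a) {
  # x: (F, M) matrix, a: per-channel slopes (length F) or scalar
  neg <- x < 0
  y <- x
  y[neg] <- (a * x)[neg]     # a recycles down columns (F fastest)
  list(out = y, neg = neg)
}

prelu_backward <- function(dout, x, a, neg, per_channel) {
  dx <- dout
  dx[neg] <- (a * dout)[neg]
  gx <- dout * x * neg
  da <- if (per_channel) rowSums(gx) else sum(gx)
  list(dx = dx, da = da)
}

softmax_rows <- function(logits) {
  # logits: (n_classes, N)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Mean softmax cross-entropy over a batch from logits; returns loss and
# d(loss)/d(logits).
softmax_ce_loss <- function(logits, y_idx) {
  N <- ncol(logits)
  p <- softmax_rows(logits)
  picked <- p[cbind(y_idx, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y_idx, seq_len(N))] <- dlogits[cbind(y_idx, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N, probs = p)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
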