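# Time-frequency frontend: Mexican-hat CWT scalograms, STFT spectrograms and
# the mean-pooling downsampler that produces the 15 x 25 per-channel model
# input from the 32 x 52 coefficient matrix.

#' Mexican hat (Ricker) mother wavelet
#'
#' \eqn{\psi(u) = \frac{2}{\sqrt{3}\,\pi^{1/4}} (1 - u^2) e^{-u^2/2}} evaluated
#' at `u = t / scale`.  Even, zero-mean, unit L2 norm at scale 1 — the second
#' derivative of a Gaussian, the standard choice for transient detection in
#' biosignals.
#'
#' @param t Dimensionless time (vectorized).
#' @param scale Positive scale factor.
#' @return Numeric vector of wavelet values.
#' @export
mexican_hat <- function(t, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    abort_invalid("`scale` must be a positive scalar")
  u <- t / scale
  (2 / (sqrt(3) * pi^0.25)) * (1 - u^2) * exp(-u^2 / 2)
}

#' Frontend configuration
#'
#' @param scales Positive ascending scale ladder in samples (default integers
#'   1..32, the simplest reproducible reading of "32 scales").
#' @param window_length Analysis window length in samples (default 52).
#' @param normalization `"printed"` uses the 1/scale prefactor of the CWT
#'   definition as printed in the source formulation; `"unit-energy"` uses the
#'   conventional 1/sqrt(scale).
#' @param standardize Optional per-channel standardization of the pooled
#'   tensors using mean/SD estimated on the training split only (off by
#'   default).
#' @return An object of class `frontend_config`.
#' @export
frontend_config <- function(scales = 1:32, window_length = 52L,
                            normalization = c("printed", "unit-energy"),
                            standardize = FALSE) {
  normalization <- match.arg(normalization)
  if (length(scales) < 1L || any(scales <= 0) || is.unsorted(scales))
    abort_invalid("`scales` must be a non-empty ascending positive vector")
  window_length <- check_count(window_length, "window_length")
  structure(list(scales = as.numeric(scales),
                 window_length = window_length,
                 normalization = normalization,
                 standardize = isTRUE(standardize)),
            class = "frontend_config")
}

cwt_norm <- function(scale, normalization) {
  switch(normalization,
         "printed" = 1 / scale,
         "unit-energy" = 1 / sqrt(scale),
         abort_invalid("unknown normalization '%s'", normalization))
}

# Dense CWT operator for an n-sample window: a (S*n) x n matrix K such that
# K %*% x, reshaped S x n (scale index fastest), is the scalogram.  Row block
# for translation b holds norm(a) * psi((t - b)/a) over t = 1..n (zero
# extension outside the window is implicit).  Memoized per (scales, n, norm).
.cwt_cache <- new.env(parent = emptyenv())

cwt_operator <- function(scales, n, normalization) {
  key <- paste(normalization, n, paste(scales, collapse = ","), sep = "|")
  hit <- .cwt_cache[[fnv1a_hex(key)]]
  if (!is.null(hit) && identical(hit$key, key)) return(hit$K)
  S <- length(scales)
  K <- matrix(0, S * n, n)
  tt <- seq_len(n)
  for (b in seq_len(n)) {
    for (s in seq_len(S)) {
      a <- scales[s]
      K[(b - 1L) * S + s, ] <- cwt_norm(a, normalization) *
        mexican_hat(tt - b, a)
    }
  }
  .cwt_cache[[fnv1a_hex(key)]] <- list(key = key, K = K)
  K
}

#' Continuous wavelet transform scalogram of one channel
#'
#' Discretizes \eqn{X(a, b) = \mathrm{norm}(a) \int x(t)\,\psi((t - b)/a)\,dt}
#' over the sample grid with zero extension beyond the window: coefficient
#' `[s, b]` is `norm(scales[s]) * sum_t x[t] * psi((t - b)/scales[s])`.
#' Linear in the signal.
#'
#' @param signal Finite numeric vector (one channel of one analysis window).
#' @param scales Ascending positive scales (default 1..32).
#' @param normalization See [frontend_config()].
#' @return An object of class `emg_scalogram`: list with `coefficients`
#'   (length(scales) x length(signal) matrix) and `scales`.
#' @export
cwt_scalogram <- function(signal, scales = 1:32,
                          normalization = c("printed", "unit-energy")) {
  normalization <- match.arg(normalization)
  if (length(signal) == 0L) abort_invalid("`signal` must be non-empty")
  if (!all(is.finite(signal))) abort_invalid("`signal` must be finite")
  if (length(scales) == 0L || any(scales <= 0))
    abort_invalid("`scales` must be non-empty and positive")
  n <- length(signal)
  K <- cwt_operator(as.numeric(scales), n, normalization)
  co <- matrix(K %*% signal, length(scales), n)
  structure(list(coefficients = co, scales = as.numeric(scales)),
            class = "emg_scalogram")
}

#' Short-time Fourier spectrogram
#'
#' Squared magnitude of the windowed DFT per frame: frames start every `hop`
#' samples, each multiplied by the taper before the DFT.  With
#' `two_sided = FALSE` (default) only bins `0..floor(L/2)` are returned.
#'
#' @param signal Finite numeric vector.
#' @param window_function `"hann"` or `"rectangular"`.
#' @param window_length Frame length L in samples (default 16).
#' @param hop Hop between frame starts (default 4).
#' @param two_sided Return all L DFT bins instead of the one-sided half.
#' @return Object of class `emg_spectrogram`: list with `power`
#'   (n_bins x n_frames, all >= 0), `window_function`, `hop`.
#' @export
stft_spectrogram <- function(signal, window_function = c("hann", "rectangular"),
                             window_length = 16L, hop = 4L,
                             two_sided = FALSE) {
  window_function <- match.arg(window_function)
  window_length <- check_count(window_length, "window_length")
  hop <- check_count(hop, "hop")
  if (window_length > length(signal))
    abort_invalid("window_length %d exceeds signal length %d",
                  window_length, length(signal))
  taper <- switch(window_function,
                  hann = 0.5 - 0.5 * cos(2 * pi * seq(0, window_length - 1) /
                                           window_length),
                  rectangular = rep(1, window_length))
  starts <- seq(1L, length(signal) - window_length + 1L, by = hop)
  frames <- vapply(starts,
                   function(s) signal[s:(s + window_length - 1L)] * taper,
                   numeric(window_length))
  frames <- matrix(frames, window_length, length(starts))
  spec <- Mod(stats::mvfft(frames))^2
  if (!two_sided) spec <- spec[seq_len(floor(window_length / 2) + 1L), ,
                               drop = FALSE]
  structure(list(power = spec, window_function = window_function, hop = hop),
            class = "emg_spectrogram")
}

# 1D mean-pooling operator: length-3 boxcar, stride 2, no padding, as a
# (floor((n-3)/2)+1) x n matrix.
pool3s2_operator <- function(n) {
  m <- floor((n - 3) / 2) + 1L
  P <- matrix(0, m, n)
  for (i in seq_len(m)) P[i, (2L * i - 1L):(2L * i + 1L)] <- 1 / 3
  P
}

#' Halve a coefficient matrix by 3x3 mean pooling
#'
#' 3x3 mean pooling with stride 2 and no padding — the halving that maps the
#' 32 x 52 scalogram exactly to the model's 15 x 25 per-channel input
#' (output shape `floor((H-3)/2)+1` by `floor((W-3)/2)+1`).
#'
#' @param mat Numeric matrix, at least 3 x 3.
#' @return Pooled matrix.
#' @export
downsample_half <- function(mat) {
  if (inherits(mat, "emg_scalogram")) mat <- mat$coefficients
  if (!is.matrix(mat) || nrow(mat) < 3L || ncol(mat) < 3L)
    abort_invalid("`mat` must be at least 3 x 3, got %s",
                  paste(dim(mat), collapse = " x "))
  pool3s2_operator(nrow(mat)) %*% mat %*% t(pool3s2_operator(ncol(mat)))
}

#' Convert one analysis window to the model input tensor
#'
#' Per channel: Mexican-hat CWT at the configured scales, then 3x3/stride-2
#' mean pooling; channels are stacked in input order.  Under defaults an
#' 8 x 52 window becomes an 8 x 15 x 25 tensor.
#'
#' @param window A [window_sample()] or channels x samples matrix.
#' @param config A [frontend_config()].
#' @return Object of class `emg_tensor`: list with `tensor` (array
#'   n_channels x pooled_rows x pooled_cols) and `gesture_label`.
#' @export
window_to_tensor <- function(window, config = frontend_config()) {
  label <- NA_character_
  if (inherits(window, "emg_window")) {
    label <- window$gesture_label
    window <- window$window
  }
  if (!is.matrix(window)) abort_invalid("`window` must be a matrix")
  arr <- windows_to_tensor_array(list(window), config)
  structure(list(tensor = array(arr, dim(arr)[1:3]), gesture_label = label),
            class = "emg_tensor")
}

# Vectorized batch frontend: list of C x n windows -> array (C, ph, pw, N).
# One BLAS multiply per chunk applies the CWT to every channel of every
# window; pooling is separable so it is two more small multiplies.
windows_to_tensor_array <- function(windows, config = frontend_config(),
                                    chunk = 256L) {
  stopifnot(length(windows) > 0L)
  w1 <- if (inherits(windows[[1]], "emg_window")) windows[[1]]$window
        else windows[[1]]
  C <- nrow(w1); n <- ncol(w1)
  if (n != config$window_length)
    abort_invalid("window has %d samples, frontend expects %d",
                  n, config$window_length)
  S <- length(config$scales)
  K <- cwt_operator(config$scales, n, config$normalization)
  A <- pool3s2_operator(S)          # pools the scale axis
  B <- pool3s2_operator(n)          # pools the time axis
  ph <- nrow(A); pw <- nrow(B)
  N <- length(windows)
  out <- array(0, c(C, ph, pw, N))
  for (lo in seq(1L, N, by = chunk)) {
    hi <- min(lo + chunk - 1L, N)
    nb <- hi - lo + 1L
    X <- matrix(0, n, C * nb)
    for (j in seq_len(nb)) {
      w <- windows[[lo + j - 1L]]
      if (inherits(w, "emg_window")) w <- w$window
      X[, ((j - 1L) * C + 1L):(j * C)] <- t(w)
    }
    SC <- K %*% X                              # (S*n) x (C*nb), scale fastest
    M1 <- A %*% matrix(SC, S, n * C * nb)      # pool scales -> (ph, n*C*nb)
    P <- aperm(array(M1, c(ph, n, C * nb)), c(2L, 1L, 3L))
    M2 <- B %*% matrix(P, n, ph * C * nb)      # pool time -> (pw, ph*C*nb)
    out[, , , lo:hi] <- aperm(array(M2, c(pw, ph, C, nb)), c(3L, 2L, 1L, 4L))
  }
  out
}

#' Build a tensor dataset from analysis windows
#'
#' Runs the CWT + pooling frontend over a list of windows and gathers the
#' results with their labels; optionally standardizes each channel using
#' statistics from a training index set only.
#'
#' @param windows List of [window_sample()] objects.
#' @param config A [frontend_config()].
#' @param train_idx Indices used to estimate per-channel mean/SD when
#'   `config$standardize` is TRUE (defaults to all windows).
#' @return Object of class `emg_tensor_dataset`: list with `tensors` (array
#'   C x ph x pw x N), `labels` (factor), `standardization`, `fingerprint`.
#' @export
build_tensor_dataset <- function(windows, config = frontend_config(),
                                 train_idx = NULL) {
  if (length(windows) == 0L) abort_invalid("no windows supplied")
  arr <- windows_to_tensor_array(windows, config)
  labels <- factor(vapply(windows, function(w) w$gesture_label, ""))
  std <- NULL
  if (config$standardize) {
    idx <- if (is.null(train_idx)) seq_along(windows) else train_idx
    C <- dim(arr)[1]
    mu <- numeric(C); sdv <- numeric(C)
    for (ch in seq_len(C)) {
      v <- arr[ch, , , idx]
      mu[ch] <- mean(v)
      sdv[ch] <- stats::sd(v)
      if (!is.finite(sdv[ch]) || sdv[ch] == 0) sdv[ch] <- 1
      arr[ch, , , ] <- (arr[ch, , , ] - mu[ch]) / sdv[ch]
    }
    std <- list(mean = mu, sd = sdv)
  }
  structure(list(tensors = arr, labels = labels, standardization = std,
                 fingerprint = config_fingerprint(unclass(config))),
            class = "emg_tensor_dataset")
}
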