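# Classical myoelectric feature sets: Hudgins time-domain (MAV/ZC/SSC/WL),
# enhanced time-domain (+ RMS + AR), NinaPro-style (RMS + TD + marginal DWT),
# and the sample-entropy pipeline (SampEn + RMS + WL).

#' Hudgins time-domain features of one channel
#'
#' * MAV — mean absolute value.
#' * ZC — zero crossings: consecutive pairs of opposite sign whose amplitude
#'   step `|x[i] - x[i+1]|` reaches `zc_threshold`.
#' * SSC — slope sign changes: interior points where
#'   `(x[i]-x[i-1]) * (x[i]-x[i+1]) > 0` and the larger neighbouring step
#'   reaches `ssc_threshold`.
#' * WL — waveform length, the summed absolute first difference.
#'
#' Thresholds default to 0 (pure sign/slope counting).
#'
#' @param x Numeric vector, length >= 3.
#' @param zc_threshold,ssc_threshold Non-negative amplitude thresholds.
#' @return Named numeric vector `c(mav, zc, ssc, wl)`.
#' @export
td_features <- function(x, zc_threshold = 0, ssc_threshold = 0) {
  if (length(x) < 3L) abort_invalid("window must have at least 3 samples")
  n <- length(x)
  d <- diff(x)
  zc <- sum(x[-n] * x[-1] < 0 & abs(d) >= zc_threshold)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  ssc <- sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= ssc_threshold)
  c(mav = mean(abs(x)), zc = zc, ssc = ssc, wl = sum(abs(d)))
}

#' Root mean square amplitude
#'
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0L) abort_invalid("`x` must be non-empty")
  sqrt(mean(x^2))
}

#' Autoregressive coefficients (Yule-Walker / Levinson-Durbin)
#'
#' Fits the linear predictor `x[t] ~ sum_k a[k] x[t-k]` by the autocorrelation
#' method: biased sample autocovariances solved through the Levinson-Durbin
#' recursion.  A zero-variance signal returns all-zero coefficients with a
#' warning.
#'
#' @param x Numeric vector with `length(x) > order`.
#' @param order AR model order (default 4, the standard myoelectric choice).
#' @return Numeric vector of `order` prediction coefficients.
#' @export
ar_coefficients <- function(x, order = 4L) {
  order <- check_count(order, "order")
  if (length(x) <= order)
    abort_invalid("need more than %d samples for AR(%d)", order, order)
  n <- length(x)
  r <- vapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n,
              0)
  if (r[1] <= 0) {
    warning("zero-variance signal; returning zero AR coefficients")
    return(rep(0, order))
  }
  a <- numeric(order)
  e <- r[1]
  for (m in seq_len(order)) {
    k <- (r[m + 1] - if (m > 1) sum(a[1:(m - 1)] * r[m:2]) else 0) / e
    a_new <- a
    a_new[m] <- k
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - k * a[(m - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of length-`m` templates
#' (indices `i != j`, both `<= N - m`) within Chebyshev distance `r`, and `A`
#' counts the same pairs extended to length `m + 1` (Richman-Moorman
#' convention, self-matches excluded).  Conventions for degenerate counts:
#' `B = 0` returns 0 (also covers constant signals), `A = 0` with `B > 0`
#' returns `Inf`.
#'
#' @param x Numeric vector with `length(x) > m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(x)` (a small epsilon if the
#'   signal is constant).
#' @return Non-negative scalar, possibly `Inf`.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  m <- check_count(m, "m")
  if (length(x) <= m + 1L)
    abort_invalid("need more than m + 1 = %d samples", m + 1L)
  if (is.null(r)) {
    s <- stats::sd(x)
    r <- if (is.finite(s) && s > 0) 0.2 * s else 1e-10
  }
  if (r <= 0) abort_invalid("`r` must be positive")
  n <- length(x)
  nt <- n - m                     # templates indexed 1 .. n - m
  # Chebyshev distance over the length-(m+1) embeddings, built lag by lag.
  dmax_m <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    v <- x[(1 + k):(nt + k)]
    dmax_m <- pmax(dmax_m, abs(outer(v, v, "-")))
  }
  v <- x[(1 + m):(nt + m)]
  dmax_m1 <- pmax(dmax_m, abs(outer(v, v, "-")))
  B <- (sum(dmax_m <= r) - nt) / 2
  A <- (sum(dmax_m1 <= r) - nt) / 2
  if (B == 0) return(0)
  if (A == 0) return(Inf)
  -log(A / B)
}

# ---------------------------------------------------------------------------
# Daubechies filters by spectral factorization.
#
# The length-2p orthonormal lowpass filter with p vanishing moments is
# h(z) = sqrt(2) * ((1+z)/2)^p * L(z), where |L(e^{iw})|^2 = P(sin^2(w/2)) and
# P(y) = sum_{k<p} C(p-1+k, k) y^k.  L is recovered as the minimum-phase
# spectral factor: roots of z^{p-1} P((2 - z - 1/z)/4) inside the unit circle.
# Computed once per order and cached; no wavelet library is required.

# Polynomial product, ascending coefficients.  Works for complex input.
polymul <- function(a, b) {
  out <- rep(if (is.complex(a) || is.complex(b)) 0i else 0,
             length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

.daub_cache <- new.env(parent = emptyenv())

daubechies_filter <- function(p) {
  p <- check_count(p, "p")
  key <- as.character(p)
  if (!is.null(.daub_cache[[key]])) return(.daub_cache[[key]])
  if (p == 1L) {
    h <- rep(1 / sqrt(2), 2)
  } else {
    bin <- choose(p - 1 + 0:(p - 1), 0:(p - 1))      # P(y) coefficients
    # z^{p-1} P((2 - z - 1/z)/4), ascending in z; note
    # (2 - z - 1/z)^k * z^k = (-(z-1)^2)^k with coefficients polymul^k(-1,2,-1)
    poly <- numeric(2 * p - 1)
    acc <- 1
    for (k in 0:(p - 1)) {
      lo <- p - k                                     # 1-based shift z^{p-1-k}
      contrib <- bin[k + 1] / 4^k * acc
      poly[lo:(lo + 2 * k)] <- poly[lo:(lo + 2 * k)] + contrib
      acc <- polymul(acc, c(-1, 2, -1))
    }
    rts <- polyroot(poly)             # ascending coefficient order
    inside <- rts[Mod(rts) < 1]
    lcoef <- 1 + 0i
    for (rt in inside) lcoef <- polymul(lcoef, c(-rt, 1))
    lcoef <- Re(lcoef)
    lcoef <- lcoef / sum(lcoef)                       # L(1) = 1
    spline <- 1
    for (i in seq_len(p)) spline <- polymul(spline, c(0.5, 0.5))
    h <- sqrt(2) * polymul(spline, lcoef)
  }
  .daub_cache[[key]] <- h
  h
}

# One DWT analysis level with zero extension: full convolution with the
# filter, then downsampling by 2 (even output indices).
dwt_level <- function(x, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)              # quadrature mirror highpass
  full_a <- polymul(x, h)
  full_d <- polymul(x, g)
  idx <- seq(2L, length(full_a), by = 2L)
  list(approx = full_a[idx], detail = full_d[idx])
}

#' Marginal discrete-wavelet-transform magnitudes
#'
#' Decomposes the channel with a Daubechies filter (db7 by default) for
#' `levels` levels (zero extension) and returns the sum of absolute detail
#' coefficients per level — the marginal summaries used in the NinaPro-style
#' feature set.
#'
#' @param x Numeric vector.
#' @param levels Number of decomposition levels (default 3).
#' @param order Daubechies vanishing moments (default 7, i.e. a 14-tap
#'   filter).
#' @return Numeric vector of length `levels`.
#' @export
dwt_marginals <- function(x, levels = 3L, order = 7L) {
  levels <- check_count(levels, "levels")
  h <- daubechies_filter(order)
  out <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    dec <- dwt_level(a, h)
    out[l] <- sum(abs(dec$detail))
    a <- dec$approx
  }
  out
}

features_per_channel <- function(set_name, ar_order = 4L, dwt_levels = 3L) {
  switch(set_name,
         td = 4L,
         enhanced_td = 4L + 1L + as.integer(ar_order),
         ninapro = 1L + 4L + as.integer(dwt_levels),
         sampen = 3L,
         abort_invalid("unknown feature set '%s'", set_name))
}

#' Extract a classical feature set from one analysis window
#'
#' Per channel, concatenated in channel order:
#' * `td` — MAV, ZC, SSC, WL (4 per channel).
#' * `enhanced_td` — TD + RMS + AR(`ar_order`) (9 per channel by default).
#' * `ninapro` — RMS + TD + `dwt_levels` marginal DWT magnitudes (8 by
#'   default).
#' * `sampen` — SampEn, RMS, WL (3 per channel).
#'
#' An infinite SampEn (no length-(m+1) matches) is replaced by the finite
#' ceiling `log((N-m) * (N-m-1))`, the largest value the pair counts could
#' have produced, so feature vectors stay finite.
#'
#' @param window A [window_sample()] or channels x samples matrix.
#' @param set_name One of `"td"`, `"enhanced_td"`, `"ninapro"`, `"sampen"`.
#' @param zc_threshold,ssc_threshold Passed to [td_features()].
#' @param ar_order AR order for `enhanced_td`.
#' @param dwt_levels DWT levels for `ninapro`.
#' @return Object of class `emg_features`: list with named `values`,
#'   `set_name`, `gesture_label`.
#' @export
extract_feature_set <- function(window,
                                set_name = c("td", "enhanced_td", "ninapro",
                                             "sampen"),
                                zc_threshold = 0, ssc_threshold = 0,
                                ar_order = 4L, dwt_levels = 3L) {
  set_name <- match.arg(set_name)
  label <- NA_character_
  if (inherits(window, "emg_window")) {
    label <- window$gesture_label
    window <- window$window
  }
  if (!is.matrix(window)) abort_invalid("`window` must be a matrix")
  C <- nrow(window)
  per <- lapply(seq_len(C), function(ch) {
    x <- window[ch, ]
    v <- switch(set_name,
      td = td_features(x, zc_threshold, ssc_threshold),
      enhanced_td = {
        td <- td_features(x, zc_threshold, ssc_threshold)
        ar <- suppressWarnings(ar_coefficients(x, ar_order))
        c(td, rms = rms(x), stats::setNames(ar, paste0("ar", seq_len(ar_order))))
      },
      ninapro = {
        td <- td_features(x, zc_threshold, ssc_threshold)
        dw <- dwt_marginals(x, dwt_levels)
        c(rms = rms(x), td, stats::setNames(dw, paste0("dwt", seq_len(dwt_levels))))
      },
      sampen = {
        se <- sample_entropy(x)
        if (!is.finite(se)) {
          nt <- length(x) - 2L
          se <- log(nt * (nt - 1))
        }
        c(sampen = se, rms = rms(x), wl = sum(abs(diff(x))))
      })
    stats::setNames(v, sprintf("ch%d_%s", ch, names(v)))
  })
  values <- do.call(c, per)
  if (!all(is.finite(values))) abort_invalid("non-finite feature produced")
  structure(list(values = values, set_name = set_name, gesture_label = label),
            class = "emg_features")
}

#' Build a feature matrix from many windows
#'
#' @inheritParams extract_feature_set
#' @param windows List of [window_sample()] objects.
#' @return List with `x` (matrix, one row per window, named columns) and
#'   `labels` (factor).
#' @export
build_feature_matrix <- function(windows,
                                 set_name = c("td", "enhanced_td", "ninapro",
                                              "sampen"), ...) {
  set_name <- match.arg(set_name)
  fv <- lapply(windows, extract_feature_set, set_name = set_name, ...)
  x <- do.call(rbind, lapply(fv, `[[`, "values"))
  labels <- factor(vapply(fv, `[[`, "", "gesture_label"))
  list(x = x, labels = labels, set_name = set_name)
}
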