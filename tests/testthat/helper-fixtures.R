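# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Small, fast synthetic benchmark for unit tests (not the acceptance scale):
# 3 gestures, 1 s x 2 repetitions, stride 10 -> 30 windows/gesture.
small_bench <- function() {
  fixture("small_bench", function() {
    synthetic_benchmark(n_gestures = 3, seed = 7,
                        duration_per_repetition = 1,
                        repetitions_per_gesture = 2,
                        stride = 10L)
  })
}

random_window <- function(n = 52, seed = 1) {
  set.seed(seed)
  rnorm(n)
}

# Direct O(S * N^2) CWT summation oracle, independent of the operator-matrix
# implementation path.
cwt_oracle <- function(signal, scales, normalization = "printed") {
  n <- length(signal)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    norm <- if (normalization == "printed") 1 / a else 1 / sqrt(a)
    for (b in seq_len(n)) {
      acc <- 0
      for (t in seq_len(n)) acc <- acc + signal[t] * mexican_hat(t - b, a)
      out[si, b] <- norm * acc
    }
  }
  out
}

# Brute-force loop oracles for the time-domain counters.
zc_oracle <- function(x, thr = 0) {
  count <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thr)
      count <- count + 1L
  }
  count
}

ssc_oracle <- function(x, thr = 0) {
  count <- 0L
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= thr) count <- count + 1L
  }
  count
}

# Naive O(N^2) sample-entropy oracle (Richman-Moorman counting).
sampen_oracle <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  cheb <- function(i, j, len) max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)]))
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (cheb(i, j, m) <= r) B <- B + 1L
      if (cheb(i, j, m + 1) <= r) A <- A + 1L
    }
  }
  if (B == 0) return(0)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Write a tiny NinaPro-style MAT fixture via the system python (scipy).
# Returns the path, or NULL if python/scipy is unavailable.
write_toy_ninapro_mat <- function(path, drop_stimulus = FALSE) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import scipy.io as sio",
    "path, drop = sys.argv[1], sys.argv[2] == '1'",
    "emg = np.arange(6*16, dtype=float).reshape(6, 16)",
    "d = {'emg': emg, 'subject': np.array([[3]])}",
    "if not drop:",
    "    d['stimulus'] = np.array([[0],[0],[1],[1],[1],[0]])",
    "sio.savemat(path, d)"), script)
  status <- system2(py, c(script, path, if (drop_stimulus) "1" else "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  path
}
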