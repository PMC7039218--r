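# Synthetic sEMG generator.
#
# Surface EMG under steady contraction is well approximated by band-limited
# stochastic noise whose envelope scales with contraction intensity.  Each
# synthetic gesture is therefore a fixed non-negative per-channel amplitude
# pattern ("activation profile") modulating independent band-limited Gaussian
# carriers, plus wide-band baseline noise.  Distinct gestures get distinct
# profiles, which is exactly the property the downstream classifiers exploit.

#' Synthetic dataset configuration
#'
#' Bundles every knob of the synthetic sEMG generator.  Defaults emulate a
#' Myo-like armband: 8 channels sampled at 200 Hz with signal energy
#' concentrated in the 20--95 Hz band.
#'
#' @param n_gestures Number of gesture classes (>= 1).
#' @param n_channels Number of electrode channels (default 8).
#' @param sample_rate Sampling rate in Hz (default 200).
#' @param duration_per_repetition Length of one gesture repetition in seconds.
#' @param repetitions_per_gesture Recordings generated per gesture.
#' @param carrier_band Two-element numeric, low/high edge of the carrier band
#'   in Hz; must lie strictly inside (0, sample_rate/2).
#' @param baseline_noise_sd Standard deviation of additive wide-band baseline
#'   noise (amplitude units).
#' @param transition_ms Linear amplitude ramp applied to the gesture component
#'   at both segment ends, in milliseconds (0 disables it).
#' @param seed Master RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_gestures,
                         n_channels = 8L,
                         sample_rate = 200,
                         duration_per_repetition = 2,
                         repetitions_per_gesture = 5L,
                         carrier_band = c(20, 95),
                         baseline_noise_sd = 0.05,
                         transition_ms = 0,
                         seed = 1L) {
  n_gestures <- check_count(n_gestures, "n_gestures")
  n_channels <- check_count(n_channels, "n_channels")
  repetitions_per_gesture <- check_count(repetitions_per_gesture,
                                         "repetitions_per_gesture")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    abort_invalid("`sample_rate` must be positive")
  if (!is.numeric(duration_per_repetition) || duration_per_repetition <= 0)
    abort_invalid("`duration_per_repetition` must be positive")
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1] || carrier_band[2] >= sample_rate / 2)
    abort_invalid("`carrier_band` must satisfy 0 < low < high < sample_rate/2")
  if (baseline_noise_sd < 0) abort_invalid("`baseline_noise_sd` must be >= 0")
  if (transition_ms < 0) abort_invalid("`transition_ms` must be >= 0")
  structure(list(n_gestures = n_gestures,
                 n_channels = n_channels,
                 sample_rate = sample_rate,
                 duration_per_repetition = duration_per_repetition,
                 repetitions_per_gesture = repetitions_per_gesture,
                 carrier_band = as.numeric(carrier_band),
                 baseline_noise_sd = baseline_noise_sd,
                 transition_ms = transition_ms,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Gesture activation profiles
#'
#' Draws one non-negative amplitude row per gesture from a seeded uniform
#' distribution on `amp_range`, greedily re-sampling any row closer (in
#' Euclidean distance) than `min_separation_floor` to an earlier row.  The
#' floor guarantees class separability for the synthetic benchmarks.
#'
#' @param n_gestures,n_channels Positive counts.
#' @param seed RNG seed; the matrix is a pure function of the arguments.
#' @param min_separation_floor Smallest admissible pairwise row distance
#'   (default 0.6, comfortably reachable in 8 dimensions for up to ~25 rows).
#' @param amp_range Amplitude range to sample from (default 0.2--1).
#' @return An `activation_matrix`: list with `values` (n_gestures x
#'   n_channels matrix) and `min_separation` (`Inf` when n_gestures == 1).
#' @export
make_activation_profiles <- function(n_gestures, n_channels, seed = 1L,
                                     min_separation_floor = 0.6,
                                     amp_range = c(0.2, 1)) {
  n_gestures <- check_count(n_gestures, "n_gestures")
  n_channels <- check_count(n_channels, "n_channels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- matrix(NA_real_, n_gestures, n_channels)
  for (g in seq_len(n_gestures)) {
    for (attempt in seq_len(10000L)) {
      row <- stats::runif(n_channels, amp_range[1], amp_range[2])
      if (g == 1L) break
      d <- sqrt(rowSums((vals[seq_len(g - 1L), , drop = FALSE] -
                           matrix(row, g - 1L, n_channels, byrow = TRUE))^2))
      if (min(d) >= min_separation_floor) break
      if (attempt == 10000L)
        abort_invalid("could not place %d separated profiles; lower the floor",
                      n_gestures)
    }
    vals[g, ] <- row
  }
  min_sep <- if (n_gestures == 1L) Inf else min(stats::dist(vals))
  structure(list(values = vals, min_separation = min_sep),
            class = "activation_matrix")
}

# Save/restore the global RNG state so generator calls do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Band-limited zero-mean Gaussian carrier of n samples, standardized to unit
# RMS.  Brick-wall FFT filter: exactly zero power outside the band and exactly
# zero phase, so segment alignment is untouched.
band_limited_carrier <- function(n, sample_rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- seq(0, n - 1) * sample_rate / n
  freq <- pmin(freq, sample_rate - freq)        # two-sided bin frequencies
  keep <- freq >= band[1] & freq <= band[2]
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

#' Generate one synthetic recording
#'
#' Each channel is `amplitude * carrier + baseline noise`, where the carrier
#' is an independent band-limited unit-RMS Gaussian process (so with zero
#' baseline noise the per-channel RMS equals the profile amplitude), and the
#' optional transition ramp scales the gesture component linearly from 0 to 1
#' over `transition_ms` at both ends.
#'
#' @param profile_row Numeric vector of per-channel amplitudes
#'   (length `config$n_channels`).
#' @param config A [synth_config()].
#' @param gesture_label Label attached to the recording.
#' @param subject_id Subject identifier string.
#' @param seed RNG seed for this recording.
#' @return A [recording()].
#' @export
generate_recording <- function(profile_row, config, gesture_label,
                               subject_id = "synthetic", seed = 1L) {
  if (!inherits(config, "synth_config"))
    abort_invalid("`config` must be a synth_config")
  if (length(profile_row) != config$n_channels)
    abort_invalid("`profile_row` has length %d, expected %d",
                  length(profile_row), config$n_channels)
  if (any(profile_row < 0)) abort_invalid("amplitudes must be non-negative")
  n <- round(config$duration_per_repetition * config$sample_rate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ramp <- rep(1, n)
  k <- round(config$transition_ms * config$sample_rate / 1000)
  if (k > 0) {
    k <- min(k, floor(n / 2))
    ramp[seq_len(k)] <- seq(0, 1, length.out = k + 1L)[-1L]
    ramp[n + 1L - seq_len(k)] <- ramp[seq_len(k)]
  }
  sig <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    gesture <- if (profile_row[ch] > 0)
      profile_row[ch] * band_limited_carrier(n, config$sample_rate,
                                             config$carrier_band) * ramp
    else rep(0, n)
    noise <- if (config$baseline_noise_sd > 0)
      stats::rnorm(n, sd = config$baseline_noise_sd) else rep(0, n)
    sig[ch, ] <- gesture + noise
  }
  recording(sig, config$sample_rate, gesture_label, subject_id)
}

#' Generate a full labelled synthetic dataset
#'
#' Draws activation profiles for `config$n_gestures` gestures and emits
#' `repetitions_per_gesture` recordings per gesture, with per-recording seeds
#' derived deterministically from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List of [recording()] objects, labels `"g01"`, `"g02"`, ...
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    abort_invalid("`config` must be a synth_config")
  prof <- make_activation_profiles(config$n_gestures, config$n_channels,
                                   seed = config$seed)
  labels <- sprintf("g%02d", seq_len(config$n_gestures))
  recs <- vector("list", config$n_gestures * config$repetitions_per_gesture)
  k <- 0L
  for (g in seq_len(config$n_gestures)) {
    for (r in seq_len(config$repetitions_per_gesture)) {
      k <- k + 1L
      recs[[k]] <- generate_recording(prof$values[g, ], config, labels[g],
                                      subject_id = "synthetic",
                                      seed = derive_seed(config$seed, k))
    }
  }
  recs
}

#' Write a recording as delimited text plus a key-value sidecar
#'
#' Layout matches what [read_delimited_recording()] expects: one row per time
#' step, one numeric column per channel, whitespace separated.  Metadata
#' (sample rate, label, subject, channel count) goes to `<path>.meta`.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  utils::write.table(t(rec$signal), path, row.names = FALSE,
                     col.names = FALSE)
  meta <- c(sprintf("n_channels %d", nrow(rec$signal)),
            sprintf("sample_rate %.10g", rec$sample_rate),
            sprintf("gesture_label %s", rec$gesture_label),
            sprintf("subject_id %s", rec$subject_id))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Write a dataset of recordings to a directory
#'
#' @param recs List of recordings.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_dataset <- function(recs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("rec_%04d.txt", seq_along(recs)))
  for (i in seq_along(recs)) write_recording(recs[[i]], paths[i])
  invisible(paths)
}
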