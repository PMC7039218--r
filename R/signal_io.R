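# Recording containers, loaders, transition trimming and window segmentation.

#' Labelled multi-channel sEMG recording
#'
#' @param signal Numeric matrix, channels x samples, all values finite.
#' @param sample_rate Sampling rate in Hz.
#' @param gesture_label Gesture label (any scalar coercible to character).
#' @param subject_id Subject identifier.
#' @return An object of class `emg_recording`.
#' @export
recording <- function(signal, sample_rate, gesture_label,
                      subject_id = "unknown") {
  if (!is.matrix(signal) || !is.numeric(signal))
    abort_invalid("`signal` must be a numeric channels x samples matrix")
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    abort_invalid("`signal` must have at least 1 channel and 1 sample")
  if (!all(is.finite(signal)))
    abort_invalid("`signal` contains non-finite values")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    abort_invalid("`sample_rate` must be positive")
  structure(list(signal = signal,
                 sample_rate = sample_rate,
                 gesture_label = as.character(gesture_label),
                 subject_id = as.character(subject_id)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d ch x %d samples @ %g Hz, label '%s', subject '%s'\n",
              nrow(x$signal), ncol(x$signal), x$sample_rate,
              x$gesture_label, x$subject_id))
  invisible(x)
}

#' One fixed-length analysis window
#'
#' @param window Numeric matrix, channels x window_length.
#' @param gesture_label Gesture label.
#' @param subject_id Source subject.
#' @param start 0-based start index of the window in its source recording
#'   (half-open interval `[start, start + window_length)`).
#' @return An object of class `emg_window`.
#' @export
window_sample <- function(window, gesture_label, subject_id = "unknown",
                          start = 0L) {
  if (!is.matrix(window) || !all(is.finite(window)))
    abort_invalid("`window` must be a finite numeric matrix")
  structure(list(window = window,
                 gesture_label = as.character(gesture_label),
                 subject_id = as.character(subject_id),
                 start = as.integer(start)),
            class = "emg_window")
}

#' Read a delimited-text recording
#'
#' One row per time step, `n_channels` numeric columns, whitespace or comma
#' separated (auto-detected).  Row order is preserved; the returned signal is
#' channels x samples.
#'
#' @param path File to read.
#' @param n_channels Expected channel count.
#' @param sample_rate Sampling rate in Hz.
#' @param gesture_label,subject_id Metadata attached to the recording.
#' @return A [recording()].
#' @export
read_delimited_recording <- function(path, n_channels, sample_rate,
                                     gesture_label, subject_id = "unknown") {
  if (!file.exists(path)) abort_invalid("file not found: %s", path)
  n_channels <- check_count(n_channels, "n_channels")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_parse("empty recording file: %s", path)
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  sig <- matrix(NA_real_, n_channels, length(lines))
  for (i in seq_along(lines)) {
    fields <- if (sep_comma) strsplit(lines[i], ",", fixed = TRUE)[[1]]
              else strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    fields <- trimws(fields)
    if (length(fields) != n_channels)
      abort_parse("line %d of %s: expected %d fields, found %d",
                  i, path, n_channels, length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      abort_parse("line %d of %s: non-numeric field", i, path)
    sig[, i] <- vals
  }
  recording(sig, sample_rate, gesture_label, subject_id)
}

#' Read a recording written by [write_recording()] using its sidecar
#'
#' @param path Path to the delimited signal file; `<path>.meta` must exist.
#' @return A [recording()].
#' @export
read_recording_with_sidecar <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) abort_invalid("missing sidecar: %s", meta_path)
  kv <- strsplit(readLines(meta_path, warn = FALSE), " ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = " "),
                                 ""),
                          vapply(kv, `[[`, "", 1L))
  for (f in c("n_channels", "sample_rate", "gesture_label", "subject_id"))
    if (is.na(meta[f])) abort_format("sidecar %s missing field '%s'",
                                     meta_path, f)
  read_delimited_recording(path,
                           n_channels = as.integer(meta["n_channels"]),
                           sample_rate = as.numeric(meta["sample_rate"]),
                           gesture_label = meta[["gesture_label"]],
                           subject_id = meta[["subject_id"]])
}

#' Read NinaPro DB5-style MAT recordings
#'
#' DB5 stores a 16-channel `emg` matrix (two stacked Myo armbands), a
#' per-sample stimulus/label vector, and subject metadata in one MAT container
#' (v5 or v7.3).  Only one armband's 8 channels are retained; the recording is
#' split into one segment per contiguous constant-label run, with label 0
#' mapped to the neutral gesture `"rest"`.
#'
#' The MAT container is decoded through the system `python` (scipy.io / h5py),
#' since no MAT reader ships with the R stack; the numeric payload crosses as
#' a temporary CSV.
#'
#' @param path MAT file path.
#' @param armband `"first"` (columns 1-8, 1-based) or `"second"` (9-16).
#' @param label_field Which label stream to segment on: `"stimulus"` (raw)
#'   or `"restimulus"` (movement-refined); the source protocol does not say
#'   which it used, so the choice is exposed.
#' @param sample_rate Sampling rate (Myo: 200 Hz).
#' @return List of [recording()] objects.
#' @export
read_ninapro_db5 <- function(path, armband = c("first", "second"),
                             label_field = c("stimulus", "restimulus"),
                             sample_rate = 200) {
  armband <- match.arg(armband)
  label_field <- match.arg(label_field)
  if (!file.exists(path)) abort_invalid("file not found: %s", path)
  raw <- mat_extract(path, label_field)
  emg <- raw$emg
  labels <- raw$labels
  subject <- raw$subject
  if (ncol(emg) < 8L)
    abort_format("emg matrix has %d channels, need at least 8", ncol(emg))
  if (armband == "second" && ncol(emg) < 16L)
    abort_invalid("armband='second' needs >= 16 channels, file has %d",
                  ncol(emg))
  cols <- if (armband == "first") 1:8 else 9:16
  emg <- emg[, cols, drop = FALSE]
  if (length(labels) != nrow(emg))
    abort_format("label vector length %d does not match %d samples",
                 length(labels), nrow(emg))
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lapply(seq_along(runs$values), function(i) {
    lab <- if (runs$values[i] == 0) "rest" else sprintf("m%02d", runs$values[i])
    recording(t(emg[starts[i]:ends[i], , drop = FALSE]),
              sample_rate, lab, subject)
  })
}

# Decode a MAT file via python into matrices R can read.  Returns list(emg,
# labels, subject).  Raises a format error naming the missing field.
mat_extract <- function(path, label_field) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) abort_format("no python interpreter available to read MAT")
  tmp_emg <- tempfile(fileext = ".csv")
  tmp_lab <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "path, emg_out, lab_out, field = sys.argv[1:5]",
    "d = None",
    "try:",
    "    import scipy.io as sio",
    "    d = sio.loadmat(path)",
    "except Exception:",
    "    import h5py",
    "    f = h5py.File(path, 'r')",
    "    d = {k: np.array(f[k]).T for k in f.keys()}",
    "for need in ('emg', field):",
    "    if need not in d:",
    "        sys.stderr.write('MISSING_FIELD:' + need)",
    "        sys.exit(3)",
    "emg = np.asarray(d['emg'], dtype=float)",
    "lab = np.asarray(d[field]).ravel().astype(int)",
    "subj = d.get('subject', None)",
    "subj = int(np.asarray(subj).ravel()[0]) if subj is not None else -1",
    "np.savetxt(emg_out, emg, delimiter=',')",
    "np.savetxt(lab_out, lab[:, None], fmt='%d')",
    "print(subj)"), script)
  out <- suppressWarnings(system2(py, c(script, path, tmp_emg, tmp_lab,
                                        label_field),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    miss <- grep("MISSING_FIELD:", out, value = TRUE)
    if (length(miss))
      abort_format("MAT file %s is missing field '%s'",
                   path, sub(".*MISSING_FIELD:", "", miss[1]))
    abort_format("failed to decode MAT file %s: %s", path,
                 paste(out, collapse = " "))
  }
  emg <- as.matrix(utils::read.csv(tmp_emg, header = FALSE))
  labels <- as.integer(readLines(tmp_lab, warn = FALSE))
  subject <- utils::tail(out, 1)
  list(emg = unname(emg), labels = labels,
       subject = sprintf("s%s", subject))
}

#' Trim gesture transitions from both ends of a recording
#'
#' Removes `round(trim_ms * sample_rate / 1000)` samples from each end,
#' leaving labels and metadata untouched.  Intended to drop the ramp-up and
#' ramp-down between successive gestures before windowing.
#'
#' @param rec A [recording()].
#' @param trim_ms Milliseconds to remove from each end (>= 0).
#' @return The trimmed [recording()].
#' @export
trim_transitions <- function(rec, trim_ms) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(trim_ms) || trim_ms < 0)
    abort_invalid("`trim_ms` must be >= 0")
  k <- round(trim_ms * rec$sample_rate / 1000)
  n <- ncol(rec$signal)
  if (k == 0) return(rec)
  if (2 * k >= n)
    abort_invalid("trimming %d samples from each end empties a %d-sample recording",
                  k, n)
  rec$signal <- rec$signal[, (k + 1L):(n - k), drop = FALSE]
  rec
}

#' Segment a recording into sliding windows
#'
#' Windows start at 0-based offsets `0, stride, 2*stride, ...`; a window is
#' emitted only if it fits entirely (`start + window_length <= n_samples`), so
#' the count is `floor((n_samples - window_length)/stride) + 1` when the
#' recording is long enough, else 0.  The default 52-sample window is 260 ms
#' at 200 Hz; the default 5-sample stride (25 ms) gives dense overlap.
#'
#' @param rec A [recording()].
#' @param window_length Window length in samples (default 52).
#' @param stride Hop between window starts in samples (default 5).
#' @return List of [window_sample()] objects (possibly empty).
#' @export
segment_windows <- function(rec, window_length = 52L, stride = 5L) {
  stopifnot(inherits(rec, "emg_recording"))
  window_length <- check_count(window_length, "window_length")
  stride <- check_count(stride, "stride")
  n <- ncol(rec$signal)
  if (n < window_length) return(list())
  starts <- seq(0L, n - window_length, by = stride)
  lapply(starts, function(s) {
    window_sample(rec$signal[, (s + 1L):(s + window_length), drop = FALSE],
                  rec$gesture_label, rec$subject_id, start = s)
  })
}

#' Segment a list of recordings
#'
#' @inheritParams segment_windows
#' @param recs List of recordings.
#' @return Flat list of [window_sample()] objects.
#' @export
segment_dataset <- function(recs, window_length = 52L, stride = 5L) {
  out <- lapply(recs, segment_windows, window_length = window_length,
                stride = stride)
  do.call(c, out)
}
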