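# High-level pipeline helpers shared by the CLI, tests and the acceptance
# script.

#' The standard synthetic gesture benchmark
#'
#' Generates a synthetic dataset at the package's stated benchmark
#' conditions — well-separated activation profiles, moderate baseline noise,
#' 2 s x 5 repetitions per gesture (350 windows per gesture at the default
#' 52/5 windowing) — segments it, runs the CWT frontend and splits 60/10/30.
#'
#' @param n_gestures Number of gesture classes (default 7).
#' @param seed Master seed driving generation and the split.
#' @param baseline_noise_sd Baseline noise level (default 0.05).
#' @param duration_per_repetition,repetitions_per_gesture Sizing knobs.
#' @param stride Window stride in samples (default 5).
#' @param frontend A [frontend_config()].  The benchmark default enables
#'   per-channel standardization (statistics from the training split): the
#'   raw printed-normalization coefficients of unit-amplitude synthetic
#'   signals are numerically small, and the fixed learning-rate/L2 policy
#'   assumes unit-scale inputs.
#' @return List with `windows`, `tensors` (`emg_tensor_dataset`), `split`,
#'   `config`.
#' @export
synthetic_benchmark <- function(n_gestures = 7L, seed = 1L,
                                baseline_noise_sd = 0.05,
                                duration_per_repetition = 2,
                                repetitions_per_gesture = 5L,
                                stride = 5L,
                                frontend = frontend_config(standardize = TRUE)) {
  cfg <- synth_config(n_gestures = n_gestures,
                      duration_per_repetition = duration_per_repetition,
                      repetitions_per_gesture = repetitions_per_gesture,
                      baseline_noise_sd = baseline_noise_sd,
                      seed = seed)
  recs <- generate_dataset(cfg)
  windows <- segment_dataset(recs, window_length = frontend$window_length,
                             stride = stride)
  labels <- vapply(windows, function(w) w$gesture_label, "")
  split <- split_dataset(labels, seed = derive_seed(seed, 1L))
  tensors <- build_tensor_dataset(windows, frontend, train_idx = split$train)
  list(windows = windows, tensors = tensors, split = split, config = cfg)
}

#' Train and evaluate EMGNet on a prepared benchmark
#'
#' @param bench Result of [synthetic_benchmark()] (or any list with
#'   `tensors` and `split`).
#' @param policy A [train_policy()].
#' @param model_seed Seed for weight initialization.
#' @param verbose Per-epoch logging.
#' @return List with `trained`, `metrics` (test-set `emg_metrics`).
#' @export
run_emgnet_benchmark <- function(bench, policy = train_policy(),
                                 model_seed = 1L, verbose = FALSE) {
  n_classes <- nlevels(bench$tensors$labels)
  model <- build_emgnet(emgnet_config(n_classes), seed = model_seed)
  trained <- train_emgnet(model, bench$tensors, bench$split, policy,
                          verbose = verbose)
  metrics <- evaluate_emgnet(trained, bench$tensors, bench$split)
  list(trained = trained, metrics = metrics)
}

#' Train and evaluate a classical baseline on a prepared benchmark
#'
#' @param bench Result of [synthetic_benchmark()].
#' @param set_name Feature set (see [extract_feature_set()]).
#' @param kind `"lda"` or `"svm"`.
#' @return List with `model`, `metrics` (test-set `emg_metrics`).
#' @export
run_baseline_benchmark <- function(bench, set_name = "td", kind = "lda") {
  fm <- build_feature_matrix(bench$windows, set_name = set_name)
  model <- fit_baseline(fm$x[bench$split$train, , drop = FALSE],
                        fm$labels[bench$split$train], kind = kind)
  pred <- predict(model, fm$x[bench$split$test, , drop = FALSE])
  metrics <- evaluate_predictions(pred, fm$labels[bench$split$test])
  list(model = model, metrics = metrics)
}
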