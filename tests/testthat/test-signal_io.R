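test_that("delimited recordings parse, round-trip and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3 4 5 6 7 8",
               "8 7 6 5 4 3 2 1",
               "1 1 1 1 1 1 1 1"), path)
  rec <- read_delimited_recording(path, 8, 200, "fist", "s1")
  expect_identical(dim(rec$signal), c(8L, 3L))
  expect_equal(rec$signal[, 1], 1:8 + 0)
  expect_equal(rec$signal[2, ], c(2, 7, 1))

  # round-trip through write_recording / sidecar reader
  cfg <- synth_config(1, duration_per_repetition = 0.5, seed = 3)
  orig <- generate_recording(runif(8), cfg, "wave", "s2", seed = 8)
  out <- withr::local_tempfile(fileext = ".txt")
  write_recording(orig, out)
  back <- read_recording_with_sidecar(out)
  expect_equal(back$signal, orig$signal, tolerance = 1e-12)
  expect_identical(back$gesture_label, "wave")
  expect_identical(back$subject_id, "s2")

  # malformed input names the offending line
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3 4 5 6 7 8", "1 2 3 4 5 6 7"), bad)
  expect_error(read_delimited_recording(bad, 8, 200, "g"),
               regexp = "line 2", class = "emgnetr_parse_error")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_delimited_recording(empty, 8, 200, "g"),
               class = "emgnetr_parse_error")
})

test_that("NinaPro MAT loader segments runs and slices armbands", {
  mat <- write_toy_ninapro_mat(tempfile(fileext = ".mat"))
  expect_false(is.null(mat))  # python + scipy are part of the supported stack
  recs <- read_ninapro_db5(mat, armband = "first")
  expect_length(recs, 3)
  expect_equal(vapply(recs, function(r) ncol(r$signal), 0), c(2, 3, 1))
  expect_equal(vapply(recs, function(r) r$gesture_label, ""),
               c("rest", "m01", "rest"))
  # armband "first" keeps 1-based columns 1..8: fixture value emg[t, c] =
  # (t-1)*16 + (c-1), so sample 1, channel 1 is 0 and channel 8 is 7
  expect_equal(recs[[1]]$signal[, 1], 0:7)
  recs2 <- read_ninapro_db5(mat, armband = "second")
  expect_equal(recs2[[1]]$signal[, 1], 8:15)

  bad <- write_toy_ninapro_mat(tempfile(fileext = ".mat"),
                               drop_stimulus = TRUE)
  expect_error(read_ninapro_db5(bad), regexp = "stimulus",
               class = "emgnetr_format_error")
})

test_that("trim_transitions removes the stated sample count", {
  rec <- recording(matrix(rnorm(8 * 400), 8), 200, "g")
  expect_identical(trim_transitions(rec, 0), rec)
  trimmed <- trim_transitions(rec, 250)
  expect_identical(ncol(trimmed$signal), 300L)        # round(0.25*200) = 50/side
  expect_equal(trimmed$signal, rec$signal[, 51:350])
  short <- recording(matrix(rnorm(8 * 100), 8), 200, "g")
  expect_error(trim_transitions(short, 300), class = "emgnetr_invalid_argument")
})

test_that("segment_windows matches the closed-form count and slices exactly", {
  rec <- recording(matrix(rnorm(8 * 104), 8), 200, "g", "s")
  w <- segment_windows(rec, 52, 52)
  expect_length(w, 2)
  expect_length(segment_windows(recording(matrix(rnorm(8 * 52), 8), 200, "g"),
                                52, 5), 1)

  rec103 <- recording(matrix(rnorm(8 * 103), 8), 200, "g")
  w103 <- segment_windows(rec103, 52, 5)
  expect_length(w103, 11)                              # floor((103-52)/5)+1
  # enumeration oracle: every admissible start, in order
  starts <- vapply(w103, function(x) x$start, 0L)
  expect_identical(starts, seq(0L, 51L, by = 5L)[seq(0, 103 - 52, by = 5) + 52 <= 103])

  # property: count formula and bit-identical slices over random shapes
  set.seed(42)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    wl <- sample(5:60, 1)
    st <- sample(1:20, 1)
    r <- recording(matrix(rnorm(2 * n), 2), 200, "g")
    ws <- segment_windows(r, wl, st)
    expected <- if (n >= wl) floor((n - wl) / st) + 1 else 0
    expect_length(ws, expected)
    if (expected > 0) {
      j <- sample(expected, 1)
      s <- ws[[j]]$start
      expect_identical(ws[[j]]$window, r$signal[, (s + 1):(s + wl)])
    }
  }
})
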