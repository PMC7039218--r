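test_that("mexican hat has the closed form, symmetry and zero mean", {
  psi0 <- 2 / (sqrt(3) * pi^0.25)
  expect_equal(mexican_hat(0), psi0, tolerance = 1e-12)
  expect_equal(mexican_hat(0), 0.8673250706, tolerance = 1e-9)
  expect_equal(mexican_hat(1), 0)
  expect_equal(mexican_hat(-1), 0)
  expect_equal(mexican_hat(0.3), mexican_hat(-0.3))
  # admissibility proxy: numeric integral vanishes
  expect_lt(abs(integrate(mexican_hat, -10, 10)$value), 1e-6)
  # sampled mean vanishes at every scale >= 2
  grid <- seq(-200, 200)
  for (a in c(2, 5, 17, 32))
    expect_lt(abs(mean(mexican_hat(grid, a))), 1e-6)
  expect_error(mexican_hat(0, scale = 0), class = "emgnetr_invalid_argument")
})

test_that("cwt_scalogram is linear and matches the direct-summation oracle", {
  z <- cwt_scalogram(rep(0, 52))
  expect_identical(dim(z$coefficients), c(32L, 52L))
  expect_true(all(z$coefficients == 0))

  x <- random_window(52, seed = 3)
  s1 <- cwt_scalogram(x)$coefficients
  s2 <- cwt_scalogram(2 * x)$coefficients
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  # unit impulse: each row is the sampled, normalized wavelet centred there
  imp <- rep(0, 52); imp[26] <- 1
  si <- cwt_scalogram(imp)$coefficients
  for (a in c(1, 7, 32))
    expect_equal(si[a, ], mexican_hat(seq_len(52) - 26, a) / a,
                 tolerance = 1e-12)

  # oracle equivalence on random signals, both normalizations, all 32 scales
  for (seed in 1:3) {
    xs <- random_window(52, seed)
    expect_equal(cwt_scalogram(xs)$coefficients,
                 cwt_oracle(xs, 1:32, "printed"), tolerance = 1e-10)
  }
  expect_equal(cwt_scalogram(x, normalization = "unit-energy")$coefficients,
               cwt_oracle(x, 1:32, "unit-energy"), tolerance = 1e-10)
  expect_error(cwt_scalogram(numeric(0)), class = "emgnetr_invalid_argument")
})

test_that("stft_spectrogram localizes tones and conserves frame energy", {
  z <- stft_spectrogram(rep(0, 64))
  expect_true(all(z$power == 0))

  # bin-centred sinusoid, rectangular window: per-frame argmax at that bin
  L <- 16; k <- 3
  x <- cos(2 * pi * k * seq(0, 127) / L)
  sp <- stft_spectrogram(x, "rectangular", L, 4)
  expect_true(all(apply(sp$power, 2, which.max) == k + 1))

  # Parseval per frame on the two-sided spectrum
  set.seed(9)
  xr <- rnorm(80)
  sp2 <- stft_spectrogram(xr, "hann", 16, 4, two_sided = TRUE)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 15) / 16)
  starts <- seq(1, 80 - 16 + 1, by = 4)
  for (f in c(1, 5, length(starts))) {
    frame <- xr[starts[f]:(starts[f] + 15)] * taper
    expect_equal(sum(sp2$power[, f]), 16 * sum(frame^2), tolerance = 1e-8)
  }
  expect_error(stft_spectrogram(rnorm(10), window_length = 16),
               class = "emgnetr_invalid_argument")
})

test_that("downsample_half implements 3x3/stride-2 mean pooling", {
  m <- matrix(rnorm(32 * 52), 32, 52)
  p <- downsample_half(m)
  expect_identical(dim(p), c(15L, 25L))
  expect_equal(downsample_half(matrix(3.7, 32, 52)),
               matrix(3.7, 15, 25), tolerance = 1e-12)
  m4 <- matrix(1:16, 4, 4)
  expect_equal(downsample_half(m4)[1, 1], mean(m4[1:3, 1:3]))
  # shape formula over random valid sizes, against direct window averaging
  set.seed(5)
  for (i in 1:10) {
    h <- sample(3:40, 1); w <- sample(3:40, 1)
    mm <- matrix(rnorm(h * w), h, w)
    pp <- downsample_half(mm)
    expect_identical(dim(pp), as.integer(c(floor((h - 3) / 2) + 1,
                                           floor((w - 3) / 2) + 1)))
    i0 <- sample(nrow(pp), 1); j0 <- sample(ncol(pp), 1)
    expect_equal(pp[i0, j0],
                 mean(mm[(2 * i0 - 1):(2 * i0 + 1), (2 * j0 - 1):(2 * j0 + 1)]))
  }
  expect_error(downsample_half(matrix(1, 2, 5)),
               class = "emgnetr_invalid_argument")
})

test_that("window_to_tensor honours shape, linearity and channel order", {
  zero <- window_to_tensor(matrix(0, 8, 52))
  expect_identical(dim(zero$tensor), c(8L, 15L, 25L))
  expect_true(all(zero$tensor == 0))

  set.seed(2)
  w <- matrix(rnorm(8 * 52), 8, 52)
  t1 <- window_to_tensor(w)$tensor
  perm <- sample(8)
  t2 <- window_to_tensor(w[perm, ])$tensor
  expect_equal(t2, t1[perm, , ], tolerance = 1e-12)
  # consistency with the per-channel scalar path
  ch <- 4
  expect_equal(t1[ch, , ],
               downsample_half(cwt_scalogram(w[ch, ])$coefficients),
               tolerance = 1e-12)
})

test_that("batch frontend equals the per-window path and standardizes on train only", {
  set.seed(3)
  ws <- lapply(1:5, function(i)
    window_sample(matrix(rnorm(8 * 52), 8, 52), sprintf("g%d", i %% 2)))
  ds <- build_tensor_dataset(ws, frontend_config())
  expect_identical(dim(ds$tensors), c(8L, 15L, 25L, 5L))
  expect_equal(ds$tensors[, , , 3], window_to_tensor(ws[[3]])$tensor,
               tolerance = 1e-12)
  dss <- build_tensor_dataset(ws, frontend_config(standardize = TRUE),
                              train_idx = 1:3)
  mu <- mean(dss$tensors[2, , , 1:3])
  expect_lt(abs(mu), 1e-10)   # training-split channel mean is removed
})
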