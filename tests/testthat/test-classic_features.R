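test_that("time-domain features match hand enumeration and loop oracles", {
  v <- td_features(c(1, -1, 1, -1))
  expect_equal(unname(v), c(1, 3, 2, 6))
  expect_equal(unname(td_features(rep(2.5, 10))), c(2.5, 0, 0, 0))
  expect_equal(unname(td_features(c(0, 1, 2, 3))), c(1.5, 0, 0, 3))

  set.seed(10)
  for (i in 1:200) {
    x <- rnorm(sample(10:60, 1))
    thr <- sample(c(0, 0.5), 1)
    v <- td_features(x, zc_threshold = thr, ssc_threshold = thr)
    expect_identical(unname(v["zc"]), as.numeric(zc_oracle(x, thr)))
    expect_identical(unname(v["ssc"]), as.numeric(ssc_oracle(x, thr)))
  }
  expect_error(td_features(c(1, 2)), class = "emgnetr_invalid_argument")
})

test_that("WL is shift-invariant, MAV is not", {
  set.seed(11)
  x <- rnorm(52)
  a <- td_features(x); b <- td_features(x + 5)
  expect_equal(a[["wl"]], b[["wl"]])
  expect_false(isTRUE(all.equal(a[["mav"]], b[["mav"]])))
})

test_that("rms has the closed form and homogeneity", {
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2, 9)), 2)
  set.seed(1)
  x <- rnorm(30)
  expect_equal(rms(-3 * x), 3 * rms(x))
  expect_error(rms(numeric(0)), class = "emgnetr_invalid_argument")
})

test_that("AR coefficients solve Yule-Walker", {
  set.seed(2)
  x <- rnorm(200)
  a1 <- ar_coefficients(x, 1)
  n <- length(x)
  r0 <- sum(x * x) / n
  r1 <- sum(x[-n] * x[-1]) / n
  expect_equal(a1, r1 / r0, tolerance = 1e-12)

  # AR(1) with phi = 0.8 recovered from a long simulation
  set.seed(3)
  xs <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  expect_lt(abs(ar_coefficients(xs, 1)[1] - 0.8), 0.05)
  expect_lt(abs(ar_coefficients(xs, 4)[1] - 0.8), 0.1)

  expect_warning(z <- ar_coefficients(rep(0, 50), 4), "zero-variance")
  expect_equal(z, rep(0, 4))
})

test_that("sample entropy matches the naive O(N^2) oracle exactly", {
  per <- rep(c(1, 2), 50)
  expect_identical(sample_entropy(per, 2, 0.1), 0)
  expect_identical(sample_entropy(rep(4, 30)), 0)   # constant: B saturates

  set.seed(4)
  for (i in 1:40) {
    x <- rnorm(sample(20:60, 1))
    r <- 0.2 * sd(x)
    expect_identical(sample_entropy(x, 2, r), sampen_oracle(x, 2, r))
  }
  x <- rnorm(40)
  expect_identical(sample_entropy(x, 3, 0.3 * sd(x)),
                   sampen_oracle(x, 3, 0.3 * sd(x)))
  expect_error(sample_entropy(c(1, 2, 3), m = 2),
               class = "emgnetr_invalid_argument")
})

test_that("daubechies filters match published constants and orthonormality", {
  h2 <- daubechies_filter(2)
  expect_equal(h2, c(-0.12940952255126, 0.224143868042013,
                     0.836516303737807, 0.482962913144534),
               tolerance = 1e-9)
  h3 <- daubechies_filter(3)
  expect_equal(h3[6], 0.332670552950083, tolerance = 1e-9)
  for (p in c(2, 3, 7)) {
    h <- daubechies_filter(p)
    expect_length(h, 2 * p)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-10)
    expect_equal(sum(h^2), 1, tolerance = 1e-10)
    for (k in seq_len(p - 1))                 # even-shift orthogonality
      expect_lt(abs(sum(h[1:(2 * p - 2 * k)] * h[(2 * k + 1):(2 * p)])), 1e-10)
  }
})

test_that("feature sets have the documented composition and order", {
  set.seed(6)
  w <- matrix(rnorm(8 * 52), 8, 52)
  expect_length(extract_feature_set(w, "td")$values, 32)
  expect_length(extract_feature_set(w, "enhanced_td")$values, 72)
  expect_length(extract_feature_set(w, "ninapro")$values, 64)
  expect_length(extract_feature_set(w, "sampen")$values, 24)
  expect_true(all(extract_feature_set(matrix(0, 8, 52), "td")$values == 0))

  # channel-order preservation: channel blocks travel with their channel
  f1 <- extract_feature_set(w, "td")$values
  f2 <- extract_feature_set(w[c(2, 1, 3:8), ], "td")$values
  expect_equal(unname(f2[1:4]), unname(f1[5:8]))
  expect_equal(unname(f2[5:8]), unname(f1[1:4]))
  # determinism
  expect_identical(extract_feature_set(w, "sampen")$values,
                   extract_feature_set(w, "sampen")$values)
  expect_error(extract_feature_set(w, "bogus"))
})

test_that("baseline classifiers separate blobs and collapse under permutation", {
  set.seed(7)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(n * 4, 6), ncol = 4))
  y <- factor(rep(c("a", "b"), each = n))
  test_x <- rbind(matrix(rnorm(40 * 4, 0), ncol = 4),
                  matrix(rnorm(40 * 4, 6), ncol = 4))
  test_y <- factor(rep(c("a", "b"), each = 40))
  for (kind in c("lda", "svm")) {
    m <- fit_baseline(x, y, kind = kind)
    expect_equal(mean(predict(m, test_x) == test_y), 1)
  }

  # permuted labels give chance-level accuracy on average; single
  # permutations fluctuate because any chance label imbalance picks up a
  # sliver of the (large) real separation, so average over replicates
  set.seed(8)
  accs <- vapply(1:15, function(i) {
    yp <- sample(y)
    m <- fit_baseline(x, yp, kind = "lda")
    mean(predict(m, test_x) == test_y)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  # training-set fit of the true model beats the chance control
  mt <- fit_baseline(x, y, kind = "lda")
  expect_gte(mean(predict(mt, x) == y), mean(accs))

  expect_error(fit_baseline(x, factor(rep("a", nrow(x)))),
               class = "emgnetr_invalid_argument")
})
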