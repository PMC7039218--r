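emgnet_param_formula <- function(widths, n_classes, in_ch = 8) {
  # independent closed-form oracle for the parameter registry
  ins <- c(in_ch, widths[1:3])
  as.integer(sum(9 * ins * widths) + sum(widths) +  # conv weights + biases
    sum(widths) +                                    # per-channel PReLU slopes
    widths[4] * n_classes + n_classes)               # 1x1 conv head
}

test_that("default 7-class EMGNet meets the exact parameter budget", {
  model <- build_emgnet(emgnet_config(7))
  expect_identical(count_parameters(model), 34311L)
  expect_lt(count_parameters(model), 67179)
  expect_identical(count_parameters(model),
                   emgnet_param_formula(model$config$conv_widths, 7))
})

test_that("parameter count follows 1x1-head arithmetic and additivity", {
  p7 <- count_parameters(build_emgnet(emgnet_config(7)))
  p8 <- count_parameters(build_emgnet(emgnet_config(8)))
  expect_identical(p8 - p7, emgnet_config(7)$conv_widths[4] + 1L)
  for (widths in list(c(4L, 4L, 8L, 8L), c(10L, 12L, 12L, 20L))) {
    m <- build_emgnet(emgnet_config(5, conv_widths = widths))
    expect_identical(count_parameters(m), emgnet_param_formula(widths, 5))
  }
})

test_that("the graph obeys the structural rules", {
  cfg <- emgnet_config(7)
  model <- build_emgnet(cfg)
  strides <- emgnetr:::emgnet_strides(cfg)
  ins <- c(cfg$in_channels, cfg$conv_widths[1:3])
  expect_identical(strides, ifelse(cfg$conv_widths > ins, 2L, 1L))
  expect_true(any(strides == 1L) && any(strides == 2L))
  for (l in 1:4)   # all body kernels are 3x3: fan-in is 9 * C_in
    expect_identical(ncol(model$params[[paste0("w", l)]]), 9L * ins[l])
  # no fully connected layer: the head acts on pooled 1x1 features only
  expect_identical(dim(model$params$wh), c(7L, cfg$conv_widths[4]))
  expect_error(emgnet_config(7, conv_widths = c(16L, 32L, 64L)),
               class = "emgnetr_invalid_argument")
})

test_that("forward pass honours shapes, determinism and head linearity", {
  model <- build_emgnet(emgnet_config(7), seed = 3)
  x <- array(rnorm(8 * 15 * 25 * 9), c(8, 15, 25, 9))
  logits <- forward_emgnet(model, x)
  expect_identical(dim(logits), c(9L, 7L))
  expect_true(all(is.finite(logits)))
  p <- exp(logits - apply(logits, 1, max))
  expect_equal(rowSums(p / rowSums(p)), rep(1, 9), tolerance = 1e-6)

  # zero-weight model: uniform softmax
  z <- model
  z$params <- lapply(z$params, function(p) p * 0)
  lz <- forward_emgnet(z, x)
  expect_true(all(lz == 0))

  # batch independence
  one <- forward_emgnet(model, array(x[, , , 4], c(8, 15, 25)))
  expect_equal(as.numeric(one), logits[4, ], tolerance = 1e-12)

  # doubling the 1x1 head weights doubles logit differences
  d <- model
  d$params$wh <- 2 * d$params$wh
  ld <- forward_emgnet(d, x)
  expect_equal(sweep(ld, 1, ld[, 1]), 2 * sweep(logits, 1, logits[, 1]),
               tolerance = 1e-10)

  expect_error(forward_emgnet(model, array(0, c(8, 15, 24))),
               regexp = "shape", class = "emgnetr_invalid_argument")
})

test_that("backprop matches numerical gradients on a small net", {
  set.seed(42)
  cfg <- emgnet_config(3, in_channels = 2, input_size = c(7, 9),
                       conv_widths = c(3L, 3L, 5L, 6L))
  m <- build_emgnet(cfg, seed = 2)
  x <- array(rnorm(2 * 7 * 9 * 4), c(2, 7, 9, 4))
  y <- sample(1:3, 4, replace = TRUE)
  fw <- emgnetr:::emgnet_forward_full(m, x, train = TRUE)
  ce <- emgnetr:::softmax_ce_loss(fw$logits, y)
  gr <- emgnetr:::emgnet_backward(m, fw, ce$dlogits)
  lossfun <- function(mm) {
    f <- emgnetr:::emgnet_forward_full(mm, x)
    emgnetr:::softmax_ce_loss(f$logits, y)$loss
  }
  eps <- 1e-6
  for (nm in c("w1", "a2", "b3", "w4", "wh", "bh")) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("cross_entropy matches its closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy(rep(1 / 5, 5), c(0, 0, 1, 0, 0)), log(5))
  expect_equal(cross_entropy(c(0.5, 0.25, 0.25), c(1, 0, 0)), log(2))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    k <- sample(4, 1)
    y <- numeric(4); y[k] <- 1
    expect_gte(cross_entropy(p, y), 0)
    expect_equal(cross_entropy(p, y), -log(p[k]))
  }
  expect_error(cross_entropy(c(0.9, 0.3), c(1, 0)),
               class = "emgnetr_invalid_argument")
  expect_error(cross_entropy(c(0.5, 0.5), c(0.5, 0.5)),
               class = "emgnetr_invalid_argument")
})
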