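# Network construction, parameter accounting, prediction contracts.

# Closed-form layer-by-layer parameter sum for the U-Net layout:
# sum(k^3 C_in C_out + C_out) over convolutions, 2^3 C_in C_out + C_out for
# the transposed convolutions, + 2C per normalization layer. Written out
# independently of the builder.
unet_param_sum <- function(w, cin = 3, k = 3, classes = 3) {
  L <- length(w)
  conv <- function(ci, co, kk = k) kk^3 * ci * co + co
  norm <- function(c) 2 * c
  total <- 0
  for (i in seq_len(L)) {
    ci <- if (i == 1) cin else w[i - 1]
    total <- total + conv(ci, w[i]) + norm(w[i]) + conv(w[i], w[i]) + norm(w[i])
  }
  for (i in seq.int(L - 1, 1)) {
    total <- total + (2^3 * w[i + 1] * w[i] + w[i]) +        # up-convolution
      conv(2 * w[i], w[i]) + norm(w[i]) + conv(w[i], w[i]) + norm(w[i])
  }
  total + (w[1] * classes + classes)                          # 1^3 head
}

test_that("parameter count matches the closed-form layer sum", {
  w8 <- c(8L, 16L, 32L, 64L)
  m <- build_network(network_config("unet3d", encoder_filters = w8))
  expect_identical(count_trainable_parameters(m), unet_param_sum(w8))
  # count from the config layout equals count over allocated arrays
  expect_identical(count_trainable_parameters(network_config("unet3d", encoder_filters = w8)),
                   as.double(count_trainable_parameters(m)))
  # doubling every width multiplies the (conv-dominated) count by ~4
  w16 <- c(16L, 32L, 64L, 128L)
  r <- unet_param_sum(w16) / unet_param_sum(w8)
  expect_lt(abs(r - 4), 0.15)
  expect_identical(count_trainable_parameters(network_config("unet3d", encoder_filters = w16)),
                   unet_param_sum(w16))
})

test_that("attention at the bottleneck strictly increases the count", {
  base <- network_config("acd_unet3d", encoder_filters = c(8L, 16L),
                         attention_bottleneck = FALSE)
  att <- network_config("acd_unet3d", encoder_filters = c(8L, 16L),
                        attention_bottleneck = TRUE)
  expect_gt(count_trainable_parameters(att), count_trainable_parameters(base))
})

test_that("nnU-Net-like widths double from 32 and respect the 320 cap", {
  for (s in 4:7) {
    cfg <- network_config("nnunet_like", n_stages = s)
    expect_identical(cfg$encoder_filters[1], 32L)
    expect_true(all(cfg$encoder_filters <= 320L))
    expect_equal(cfg$encoder_filters, pmin(32 * 2^(seq_len(s) - 1), 320),
                 ignore_attr = TRUE)
  }
  expect_identical(network_config("nnunet_like")$normalization, "instance")
  expect_identical(network_config("nnunet_like")$nonlinearity, "leaky_relu")
})

test_that("invalid configurations are rejected", {
  expect_error(network_config("unet3d", encoder_filters = c(64L, 32L)),
               "strictly increase")
  m <- build_network(network_config("unet3d", encoder_filters = c(8L, 16L, 32L, 64L)))
  expect_error(adiposeg:::net_forward(m, array(0, c(8, 8, 8, 3))), "too small")
  expect_error(adiposeg:::net_forward(m, array(0, c(32, 32, 16, 2))), "channels")
})

test_that("probability maps have the input grid and normalized classes", {
  m <- build_network(network_config("unet3d", encoder_filters = c(4L, 8L), seed = 5L))
  x <- array(abs(rnorm(16 * 16 * 8 * 3)), c(16, 16, 8, 3))
  p <- adiposeg:::net_predict_probs(m, x)
  expect_identical(dim(p), c(16L, 16L, 8L, 3L))
  sums <- apply(p, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0))
  # shapes not divisible by the pooling factors are padded and cropped back
  x2 <- array(abs(rnorm(15 * 13 * 7 * 3)), c(15, 13, 7, 3))
  p2 <- adiposeg:::net_predict_probs(m, x2)
  expect_identical(dim(p2), c(15L, 13L, 7L, 3L))
})

test_that("prediction is deterministic and stays in the label set", {
  s <- generate_subject(tiny_spec(nx = 32L, sat_thickness_mm = 40,
                                  sat_modulation = 0.1, seed = 3L))
  m <- build_network(network_config("acd_unet3d", encoder_filters = c(4L, 8L), seed = 1L))
  p1 <- predict_mask(m, s$volume)
  p2 <- predict_mask(m, s$volume)
  expect_identical(p1$labels, p2$labels)
  expect_true(all(p1$labels %in% 0:2))
  expect_identical(dim(p1$labels), dim(s$mask$labels))
})

test_that("the fully convolutional U-Net is equivariant to period shifts", {
  # compact blob in a zero field, shifted by one full pooling period (2 for
  # a 2-level net); supports stay clear of the boundary so zero padding is
  # never informative
  m <- build_network(network_config("unet3d", encoder_filters = c(4L, 8L), seed = 2L))
  dims <- c(40L, 40L, 16L, 3L)
  x <- array(0, dims)
  cx <- 18:22
  x[cx, cx, 7:9, ] <- 1
  shift <- 2L
  x2 <- array(0, dims)
  x2[cx + shift, cx, 7:9, ] <- 1
  y1 <- adiposeg:::net_forward(m, x)$v
  y2 <- adiposeg:::net_forward(m, x2)$v
  core <- 10:30
  expect_equal(y2[core + shift, core, 5:11, ], y1[core, core, 5:11, ],
               tolerance = 1e-8)
})

test_that("checkpoints round-trip through save and load", {
  m <- build_network(network_config("acd_unet3d", encoder_filters = c(4L, 8L), seed = 7L))
  x <- array(abs(rnorm(16 * 16 * 8 * 3)), c(16, 16, 8, 3))
  p <- adiposeg:::net_predict_probs(m, x)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$config$arch, "acd_unet3d")
  expect_equal(adiposeg:::net_predict_probs(m2, x), p, tolerance = 1e-12)
})
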