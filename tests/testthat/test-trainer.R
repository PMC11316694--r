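# Input normalization, stratified splitting, the training loop and
# evaluation orchestration.

test_that("rescale and z-score normalization meet their contracts", {
  set.seed(1)
  x <- array(abs(rnorm(16^3, 50, 20)), c(16, 16, 16))
  r <- normalize_volume(x, "rescale_0_255")
  expect_equal(min(r), 0, tolerance = 1e-12)
  expect_equal(max(r), 255, tolerance = 1e-12)
  z <- normalize_volume(x, "zscore")
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  # z-scoring is invariant to affine input transforms
  z2 <- normalize_volume(3.7 * x + 11, "zscore")
  expect_equal(z2, z, tolerance = 1e-8)
  # constant volumes map to zeros, not errors
  k <- array(5, c(4, 4, 4))
  expect_true(all(normalize_volume(k, "rescale_0_255") == 0))
  expect_true(all(normalize_volume(k, "zscore") == 0))
  # per-channel on multi-contrast volumes
  s <- generate_subject(tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40,
                                  sat_modulation = 0.1, seed = 2L))
  vn <- normalize_volume(s$volume, "rescale_0_255")
  for (ch in vn$channels) expect_equal(range(ch), c(0, 255), tolerance = 1e-12)
})

make_manifest <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 2),
             timepoint = rep(1:2, n),
             adiposity_score = rep(rnorm(n, 1, 0.15), each = 2),
             age_like = rep(rnorm(n, 50, 14), each = 2))
}

test_that("split sizes follow largest-remainder rounding", {
  man <- split_cohort(make_manifest(10), seed = 3L)
  sizes <- table(man$split[man$timepoint == 1])
  expect_identical(as.integer(sizes[c("train", "val", "test")]), c(7L, 1L, 2L))
  expect_error(split_cohort(make_manifest(10), fractions = c(0.6, 0.1, 0.2)),
               "sum to 1")
  expect_error(split_cohort(make_manifest(6)), "at least 10")
})

test_that("both timepoints share the subject's split and covariates balance", {
  man <- split_cohort(make_manifest(200), seed = 5L)
  per_sub <- tapply(man$split, man$subject_id, function(x) length(unique(x)))
  expect_true(all(per_sub == 1))
  bal <- attr(man, "balance")
  expect_true(all(bal$kruskal_wallis_p > 0.05))
  # balance verified independently through the stats layer
  kw <- kruskal_wallis(split(man$adiposity_score[man$timepoint == 1],
                             man$split[man$timepoint == 1]))
  expect_gt(kw$p, 0.05)
})

test_that("training is reproducible and checkpoints the best epoch", {
  s1 <- generate_subject(tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40,
                                   sat_modulation = 0.1, seed = 1L))
  s2 <- generate_subject(tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40,
                                   sat_modulation = 0.1, seed = 2L))
  cfgn <- network_config("unet3d", encoder_filters = c(4L, 8L), seed = 4L)
  tc <- train_config(loss = loss_config("WDL"), lr = 1e-3, epochs = 3, seed = 8L)
  f1 <- train_network(build_network(cfgn), list(s1), list(s2), tc)
  f2 <- train_network(build_network(cfgn), list(s1), list(s2), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best_epoch, which.min(f1$history$val_loss))
  # returned weights reproduce the recorded minimum validation loss
  P <- adiposeg:::net_predict_probs(
    f1$model, adiposeg:::sample_to_input(s2, "rescale_0_255", 3L))
  vloss <- adiposeg:::loss_eval(P, s2$mask$labels, tc$loss)$loss
  expect_equal(vloss, min(f1$history$val_loss), tolerance = 1e-10)
})

test_that("a small U-Net can overfit one phantom", {
  s <- generate_subject(tiny_spec(nx = 32L, nz = 16L, sat_thickness_mm = 40,
                                  sat_modulation = 0.1, noise_sigma = 4,
                                  seed = 9L))
  model <- build_network(network_config("unet3d",
                                        encoder_filters = c(8L, 16L, 32L, 64L),
                                        seed = 2L))
  # capacity check: training loss must fall below 0.05 within 200 epochs;
  # stop as soon as it does to keep the run short
  tc <- train_config(loss = loss_config("WDL"), lr = 2e-3, epochs = 40, seed = 3L)
  reached <- FALSE
  for (round in 1:5) {                       # up to 200 epochs in rounds of 40
    fit <- train_network(model, list(s), list(s), tc)
    model <- fit$model
    if (min(fit$history$train_loss) < 0.05) { reached <- TRUE; break }
  }
  expect_true(reached)
})

test_that("evaluation passes an oracle model through with perfect scores", {
  specs <- lapply(1:3, function(i) tiny_spec(nx = 32L, nz = 8L,
                                             sat_thickness_mm = 40,
                                             sat_modulation = 0.1, seed = i))
  subs <- lapply(seq_along(specs), function(i) {
    s <- generate_subject(specs[[i]], seed = i, subject_id = sprintf("t%d", i))
    s
  })
  masks <- lapply(subs, `[[`, "mask")
  names(masks) <- vapply(subs, function(s) s$volume$subject_id, "")
  oracle <- function(vol) masks[[vol$subject_id]]
  ev <- evaluate_cohort(NULL, subs, predict_fn = oracle)
  expect_true(all(ev$dice_sat == 1))
  expect_true(all(ev$dice_vat == 1))
  expect_true(all(ev$fp_pct == 0))
  expect_true(all(ev$fn_pct == 0))
  expect_equal(ev$pred_sat_mL, ev$ref_sat_mL)
})

test_that("split leakage between train and test is a hard error", {
  s <- generate_subject(tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40,
                                  sat_modulation = 0.1, seed = 1L),
                        subject_id = "leaky")
  expect_error(evaluate_cohort(NULL, list(s), train_ids = c("leaky", "other"),
                               predict_fn = function(v) s$mask),
               "leakage.*leaky")
})

test_that("the no-augmentation pipeline delivers identical batches per seed", {
  s <- generate_subject(tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40,
                                  sat_modulation = 0.1, seed = 1L))
  x1 <- adiposeg:::sample_to_input(s, "rescale_0_255", 3L)
  x2 <- adiposeg:::sample_to_input(s, "rescale_0_255", 3L)
  expect_identical(x1, x2)
})
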