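# Synthetic Dixon phantom generator: determinism, label structure, signal
# model, analytic volume agreement, longitudinal pairing, cohort sampling.

test_that("generation is deterministic and labels are exclusive", {
  spec <- tiny_spec(seed = 11L)
  a <- generate_subject(spec, seed = 11L)
  b <- generate_subject(spec, seed = 11L)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$volume$channels, b$volume$channels)
  expect_true(all(a$mask$labels %in% 0:2))
  c <- generate_subject(spec, seed = 12L)
  expect_false(identical(a$volume$channels$fat, c$volume$channels$fat))
})

test_that("zero VAT fill yields an empty VAT class", {
  s <- generate_subject(tiny_spec(vat_fill_fraction = 0))
  expect_identical(sum(s$mask$labels == 2L), 0L)
  expect_identical(s$truth$vat_volume_mL, 0)
})

test_that("invalid specs are rejected", {
  expect_error(tiny_spec(vat_fill_fraction = 1.2), "vat_fill_fraction")
  expect_error(tiny_spec(sat_thickness_mm = 3), "alias")
  expect_error(phantom_spec(matrix_size = c(192L, 192L, 51L),
                            torso_axes_mm = c(199, 125)), "margin")
})

test_that("noise-free contrast properties hold", {
  spec <- tiny_spec(noise_sigma = 0, include_ip = TRUE, seed = 3L)
  s <- generate_subject(spec, seed = 3L)
  ch <- s$volume$channels
  lab <- s$mask$labels
  adipose <- lab == 1L | lab == 2L
  expect_true(all(ch$fat[adipose] > ch$water[adipose]))
  lean <- ch$water > 0
  expect_true(all(ch$water[lean] >= ch$fat[lean]))
  expect_equal(ch$ip, ch$water + ch$fat, tolerance = 1e-12)
  # opposed-phase is the absolute water-fat difference
  expect_equal(ch$op, abs(ch$water - ch$fat), tolerance = 1e-12)
})

test_that("fat-bright confounders are present and labeled background", {
  spec <- tiny_spec(noise_sigma = 0, seed = 4L, confounders = TRUE)
  s <- generate_subject(spec, seed = 4L)
  ch <- s$volume$channels
  conf_vox <- ch$fat > ch$water & s$mask$labels == 0L
  # the vertebral cylinder spans every slice, so this set is large and
  # present on each slice
  expect_gt(sum(conf_vox), 100)
  expect_true(all(apply(conf_vox, 3, any)))
  # confounder intensity equals the SAT fat signal exactly (no threshold
  # separates them)
  expect_equal(max(ch$fat[conf_vox]), spec$fat_signal)
  # disabling confounders removes them
  s2 <- generate_subject(tiny_spec(noise_sigma = 0, seed = 4L, confounders = FALSE),
                         seed = 4L)
  expect_identical(sum(s2$volume$channels$fat > s2$volume$channels$water &
                         s2$mask$labels == 0L), 0L)
})

test_that("VAT fill fraction target is met", {
  spec <- tiny_spec(nx = 64L, vat_fill_fraction = 0.3, noise_sigma = 0, seed = 8L)
  s <- generate_subject(spec, seed = 8L)
  lab <- s$mask$labels
  ch <- s$volume$channels
  cavity_free <- (ch$water > 0) | (lab == 2L)   # lean organs + VAT
  frac <- sum(lab == 2L) / sum(cavity_free)
  expect_lt(abs(frac - 0.3), 0.005)
})

test_that("voxel-count SAT volume matches the closed-form annulus volume", {
  s <- generate_subject(circular_spec(), seed = 2L)
  expected <- annulus_volume_mL(R = 120, t = 20, n_slices = 51, dz = 5)
  expect_equal(s$truth$analytic_sat_volume_mL, expected, tolerance = 1e-10)
  expect_lt(abs(s$truth$sat_volume_mL - expected) / expected, 0.03)
})

test_that("voxelization error shrinks as the grid is refined", {
  coarse <- generate_subject(circular_spec(nx = 96L, nz = 17L), seed = 2L)
  fine <- generate_subject(circular_spec(nx = 192L, nz = 17L), seed = 2L)
  expected <- annulus_volume_mL(120, 20, 17, 5)
  err_c <- abs(coarse$truth$sat_volume_mL - expected) / expected
  err_f <- abs(fine$truth$sat_volume_mL - expected) / expected
  expect_lt(err_f, err_c)
})

test_that("longitudinal pair with zero delta and zero noise is unchanged", {
  spec <- circular_spec(nx = 96L, nz = 17L)
  pr <- generate_longitudinal_pair(spec, delta = c(0, 0), seed = 6L)
  expect_identical(unname(pr$true_delta_mL["sat"]), 0)
  expect_identical(unname(pr$true_delta_mL["vat"]), 0)
  expect_identical(pr$tp1$mask$labels, pr$tp2$mask$labels)
})

test_that("longitudinal deltas have the commanded signs and magnitude", {
  spec <- circular_spec(nx = 96L, nz = 17L)
  pr <- generate_longitudinal_pair(spec, delta = c(0.10, -0.20), seed = 6L)
  expect_gt(pr$true_delta_mL["sat"], 0)
  expect_lt(pr$true_delta_mL["vat"], 0)
  # SAT change vs the closed-form annulus difference, at the acquisition
  # in-plane resolution (a 2 mm shell change needs the 2.08 mm grid)
  pr2 <- generate_longitudinal_pair(circular_spec(nx = 192L, nz = 17L),
                                    delta = c(0.10, 0), seed = 6L)
  expected <- annulus_volume_mL(120, 22, 17, 5) - annulus_volume_mL(120, 20, 17, 5)
  expect_lt(abs(pr2$true_delta_mL["sat"] - expected) / expected, 0.05)
  expect_error(generate_longitudinal_pair(spec, delta = c(0.95, 0)), "delta")
})

test_that("cohort manifests have one row per subject and timepoint", {
  spec <- tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40, sat_modulation = 0.1)
  man <- generate_cohort(4, spec = spec, seed = 5L, keep_data = FALSE)
  expect_identical(nrow(man), 8L)
  expect_identical(sort(unique(man$timepoint)), c(1L, 2L))
  expect_identical(anyDuplicated(paste(man$subject_id, man$timepoint)), 0L)
  man2 <- generate_cohort(4, spec = spec, seed = 9L, keep_data = FALSE)
  expect_false(identical(man$adiposity_score, man2$adiposity_score))
  expect_error(generate_cohort(0, spec = spec), "n must be")
})

test_that("cohort covariate sampling matches its stated distribution", {
  spec <- tiny_spec(nx = 32L, nz = 8L, sat_thickness_mm = 40, sat_modulation = 0.1)
  man <- generate_cohort(50, spec = spec, seed = 7L, keep_data = FALSE,
                         adiposity = c(mean = 1, sd = 0.1))
  ad <- man$adiposity_score[man$timepoint == 1L]
  # standard-error bound: |mean - mu| < 3 sd / sqrt(n)
  expect_lt(abs(mean(ad) - 1), 3 * 0.1 / sqrt(50))
})
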