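# Segmentation metrics vs brute-force voxel-loop oracles, ICC against the
# ANOVA mean-squares definition, longitudinal regression, and the rank
# statistics layer.

test_that("dice3d handles identity, the flat toy case, and double emptiness", {
  lab <- random_mask()
  expect_identical(dice3d(lab, lab, 1L), 1)
  # flattened toy: pred = [1,1,0], ref = [1,0,0] -> 2/3
  pred <- array(c(1L, 1L, 0L), c(3, 1, 1))
  ref <- array(c(1L, 0L, 0L), c(3, 1, 1))
  expect_equal(dice3d(pred, ref, 1L), 2 / 3, tolerance = 1e-12)
  empty <- array(0L, c(3, 1, 1))
  expect_message(d <- dice3d(empty, empty, 2L), "empty in both")
  expect_identical(d, 1)
  expect_error(dice3d(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 3)), 1L),
               "grids differ")
})

test_that("the four-voxel worked FP/FN example evaluates to 40% and 33.3%", {
  # indicator form of the pooled rates: r_SAT = [1,1,0,0], r_VAT = [0,0,1,0];
  # p_SAT = [1,0,0,1], p_VAT = [0,0,1,1] (the prediction indicators overlap
  # at voxel 4, which the indicator interface permits)
  ref <- list(sat = c(1, 1, 0, 0), vat = c(0, 0, 1, 0))
  pred <- list(sat = c(1, 0, 0, 1), vat = c(0, 0, 1, 1))
  r <- fp_fn_rates(pred, ref)
  # FP: 2 pooled false positives over 5 pooled reference negatives; FN: 1/3
  expect_equal(unname(r["fp_pct"]), 40, tolerance = 1e-12)
  expect_equal(unname(r["fn_pct"]), 100 / 3, tolerance = 1e-12)
  # the same arithmetic through exclusive label masks
  refm <- array(c(1L, 1L, 2L, 0L), c(4, 1, 1))
  predm <- array(c(1L, 0L, 2L, 1L), c(4, 1, 1))
  rm_ <- fp_fn_rates(predm, refm)
  expect_equal(unname(rm_["fp_pct"]), 100 * 1 / 5, tolerance = 1e-12)
  expect_equal(unname(rm_["fn_pct"]), 100 * 1 / 3, tolerance = 1e-12)
})

test_that("metrics equal their brute-force voxel-loop oracles exactly", {
  set.seed(42)
  vs <- c(2.08, 2.08, 5)
  for (i in 1:25) {
    pred <- random_mask()
    ref <- random_mask()
    for (cl in 1:2) {
      expect_identical(dice3d(pred, ref, cl), dice_loop(pred, ref, cl))
    }
    r <- fp_fn_rates(pred, ref)
    o <- fpfn_loop(pred, ref)
    expect_identical(unname(r["fp_pct"]), unname(o["fp"]))
    expect_identical(unname(r["fn_pct"]), unname(o["fn"]))
    expect_equal(mask_volume(pred, 1L, vs), volume_loop(pred, 1L, vs),
                 tolerance = 1e-15)
  }
})

test_that("dice is symmetric and FP/FN swap under argument exchange", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_mask(); b <- random_mask()
    expect_identical(dice3d(a, b, 1L), dice3d(b, a, 1L))
    expect_identical(dice3d(a, b, 2L), dice3d(b, a, 2L))
    r1 <- fp_fn_rates(a, b)
    r2 <- fp_fn_rates(b, a)
    # the pooled error counts swap roles under argument exchange:
    # FP_num(a,b) = sum_cl #{a = cl & b != cl} = FN_num(b,a)
    N <- length(a)
    posa <- sum(a == 1) + sum(a == 2); posb <- sum(b == 1) + sum(b == 2)
    expect_equal(r1[["fp_pct"]] / 100 * (2 * N - posb),
                 r2[["fn_pct"]] / 100 * posa, tolerance = 1e-9)
    expect_equal(r1[["fn_pct"]] / 100 * posb,
                 r2[["fp_pct"]] / 100 * (2 * N - posa), tolerance = 1e-9)
  }
})

test_that("mask volumes follow the voxel arithmetic and are additive", {
  lab <- array(0L, c(10L, 10L, 10L))
  lab[seq_len(1000)[1:1000]] <- 1L
  expect_equal(mask_volume(lab, 1L, c(2.08, 2.08, 5)), 1000 * 21.632 / 1000,
               tolerance = 1e-12)
  a <- array(0L, c(4, 4, 4)); a[1:10] <- 1L
  b <- array(0L, c(4, 4, 4)); b[20:40] <- 1L
  ab <- a; ab[20:40] <- 1L
  vs <- c(1, 2, 3)
  expect_equal(mask_volume(ab, 1L, vs),
               mask_volume(a, 1L, vs) + mask_volume(b, 1L, vs))
  expect_identical(mask_volume(array(0L, c(4, 4, 4)), 2L, vs), 0)
})

test_that("ICC matches the ANOVA oracle and orders agreement < consistency", {
  a <- c(10, 12, 14, 16, 18)
  b <- a + 5                                  # constant offset >> spread? no: comparable
  r_ag <- icc_agreement(a, b, "agreement")
  r_co <- icc_agreement(a, b, "consistency")
  expect_equal(r_ag$icc, icc_oracle(a, b, "agreement"), tolerance = 1e-12)
  expect_equal(r_co$icc, icc_oracle(a, b, "consistency"), tolerance = 1e-12)
  expect_lt(r_ag$icc, r_co$icc)
  expect_equal(r_co$icc, 1, tolerance = 1e-12)  # perfect consistency
  ident <- icc_agreement(a, a)
  expect_equal(ident$icc, 1, tolerance = 1e-12)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-10)
})

test_that("ICC categories use the published cutpoints", {
  set.seed(1)
  a <- rnorm(50, 100, 20)
  # noise levels spanning the agreement spectrum; the reported category
  # must match the printed cutpoints applied to the reported ICC
  for (sdn in c(1, 10, 25, 60)) {
    r <- icc_agreement(a, a + rnorm(50, 0, sdn))
    want <- if (r$icc < 0.5) "poor" else if (r$icc < 0.75) "moderate"
            else if (r$icc <= 0.9) "good" else "excellent"
    expect_identical(r$category, want)
  }
  # a 0.93-grade agreement (tight noise) lands in "excellent"
  r <- icc_agreement(a, a + rnorm(50, 0, 1))
  expect_gt(r$icc, 0.9)
  expect_identical(r$category, "excellent")
})

test_that("ICC approaches Pearson r without bias at equal variance", {
  set.seed(2)
  a <- rnorm(200)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(200)
  r <- icc_agreement(a, b)$icc
  expect_lt(abs(r - cor(a, b)), 0.05)
  expect_lte(icc_agreement(a, b)$icc, 1)
})

test_that("longitudinal delta regression recovers identity and noise limits", {
  df1 <- data.frame(subject_id = paste0("s", 1:8),
                    ref_sat_mL = seq(1000, 2400, 200),
                    ref_vat_mL = seq(500, 1200, 100))
  df1$pred_sat_mL <- df1$ref_sat_mL
  df1$pred_vat_mL <- df1$ref_vat_mL
  df2 <- df1
  df2$ref_sat_mL <- df1$ref_sat_mL * seq(0.9, 1.11, 0.03)
  df2$ref_vat_mL <- df1$ref_vat_mL * seq(1.1, 0.89, -0.03)
  df2$pred_sat_mL <- df2$ref_sat_mL
  df2$pred_vat_mL <- df2$ref_vat_mL
  r <- delta_volume_analysis(df1, df2)
  expect_equal(r$sat_slope, 1, tolerance = 1e-10)
  expect_equal(r$sat_intercept, 0, tolerance = 1e-8)
  expect_equal(r$vat_slope, 1, tolerance = 1e-10)
  # small prediction noise keeps the slope near 1
  set.seed(3)
  df2n <- df2
  df2n$pred_sat_mL <- df2$pred_sat_mL + rnorm(8, 0, 1)
  rn <- delta_volume_analysis(df1, df2n)
  expect_lt(abs(rn$sat_slope - 1), 0.1)
  # a missing subject is an error naming it
  expect_error(delta_volume_analysis(df1, df2[-3, ]), "s3")
})

test_that("wilcoxon handles degenerate pairs per the zero-discard rule", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  r <- wilcoxon_signed_rank(x, x)
  expect_identical(r$p, 1)
  expect_identical(r$n_nonzero, 0L)
  r2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 6), c(2, 3, 4, 5, 1))
  expect_true(r2$p > 0 && r2$p <= 1)
})

test_that("BH matches its step-up definition", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_identical(r$n_rejected, 4L)          # largest i with p(i) <= i*0.0125 is 4
  set.seed(5)
  for (i in 1:50) {
    m <- sample(3:12, 1)
    p <- round(runif(m)^2, 3)
    r <- benjamini_hochberg(p, q = 0.05)
    expect_identical(r$reject, bh_oracle(p, 0.05))
    # monotone: adjusted p non-decreasing in raw rank; larger q rejects more
    o <- order(p)
    expect_true(all(diff(r$adjusted[o]) >= -1e-12))
    r2 <- benjamini_hochberg(p, q = 0.1)
    expect_gte(r2$n_rejected, r$n_rejected)
  }
})

test_that("kruskal-wallis holds its type-I error under the null", {
  set.seed(11)
  rej <- 0L
  nrep <- 1000L
  for (i in seq_len(nrep)) {
    g <- list(rnorm(12), rnorm(12), rnorm(12))
    if (kruskal_wallis(g)$p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / nrep
  band <- 3 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rate - 0.05), band + 1e-9)
})
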