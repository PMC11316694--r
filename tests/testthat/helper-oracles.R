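# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain voxel loops / direct definitional arithmetic so
# they share no code with the implementation they check.

# 3D Dice by explicit voxel loop
dice_loop <- function(pred, ref, cl) {
  inter <- 0L; np <- 0L; nr <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == cl
    r <- ref[i] == cl
    if (p && r) inter <- inter + 1L
    if (p) np <- np + 1L
    if (r) nr <- nr + 1L
  }
  if (np + nr == 0L) return(1)
  2 * inter / (np + nr)
}

# Pooled FP/FN by explicit voxel loop over the one-hot channels
fpfn_loop <- function(pred, ref) {
  fp_num <- 0L; fp_den <- 0L; fn_num <- 0L; fn_den <- 0L
  for (cl in 1:2) {
    for (i in seq_along(pred)) {
      r <- ref[i] == cl
      p <- pred[i] == cl
      if (!r) {
        fp_den <- fp_den + 1L
        if (p) fp_num <- fp_num + 1L
      } else {
        fn_den <- fn_den + 1L
        if (!p) fn_num <- fn_num + 1L
      }
    }
  }
  c(fp = 100 * fp_num / fp_den, fn = 100 * fn_num / fn_den)
}

volume_loop <- function(mask, cl, vs) {
  n <- 0L
  for (i in seq_along(mask)) if (mask[i] == cl) n <- n + 1L
  n * vs[1] * vs[2] * vs[3] / 1000
}

# Weighted soft Dice by direct summation (voxel weights included in all
# three sums), for checking FBDL against its definition.
soft_dice_oracle <- function(probs, lab, classes, w, m, eps) {
  loss <- 1
  for (j in seq_along(classes)) {
    num <- eps; pden <- 0; rden <- 0
    for (i in seq_along(lab)) {
      p <- probs[i + (classes[j]) * length(lab)]
      r <- as.numeric(lab[i] == classes[j])
      num <- num + 2 * m[i] * p * r
      pden <- pden + m[i] * p
      rden <- rden + m[i] * r
    }
    loss <- loss - w[j] * num / (pden + rden + eps)
  }
  loss
}

# BH step-up by literal definition
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# ICC from explicitly written two-way ANOVA mean squares (k = 2 raters)
icc_oracle <- function(a, b, type = "agreement") {
  n <- length(a)
  x <- cbind(a, b)
  grand <- mean(x)
  ms_rows <- 2 * sum((rowMeans(x) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(x) - grand)^2) / 1
  ss_err <- sum((x - grand)^2) - 2 * sum((rowMeans(x) - grand)^2) -
    n * sum((colMeans(x) - grand)^2)
  ms_err <- ss_err / (n - 1)
  if (type == "agreement") {
    (ms_rows - ms_err) / (ms_rows + ms_err + 2 * (ms_cols - ms_err) / n)
  } else {
    (ms_rows - ms_err) / (ms_rows + ms_err)
  }
}

random_mask <- function(dims = c(8L, 8L, 8L)) {
  array(sample(0:2, prod(dims), replace = TRUE), dims)
}

# Small phantom spec used across tests (400 mm FOV at reduced matrix)
tiny_spec <- function(nx = 48L, nz = 16L, ...) {
  phantom_spec(matrix_size = c(nx, nx, nz),
               voxel_size_mm = c(400 / nx, 400 / nx, 5), ...)
}

# Uniform circular annulus phantom: closed-form SAT volume available
circular_spec <- function(nx = 192L, nz = 51L, R = 120, t = 20, noise = 0, ...) {
  phantom_spec(matrix_size = c(nx, nx, nz),
               voxel_size_mm = c(400 / nx, 400 / nx, 5),
               torso_axes_mm = c(R, R), torso_taper = 0,
               sat_thickness_mm = t, sat_modulation = 0,
               noise_sigma = noise, ...)
}

# Closed-form annulus volume in mL: pi (R^2 - (R - t)^2) per-slice area
# times the stack extent
annulus_volume_mL <- function(R, t, n_slices, dz) {
  pi * (R^2 - (R - t)^2) * n_slices * dz / 1000
}
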