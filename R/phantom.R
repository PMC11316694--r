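# Synthetic two-point-Dixon abdominal phantom.
#
# Each subject is an axial stack of elliptical torso cross-sections: a
# subcutaneous fat ring (SAT, label 1) of spatially varying thickness, an
# inner cavity of water-dominant lean tissue holding spatially scattered
# visceral fat components (VAT, label 2), and fat-bright confounders (a
# vertebral marrow cylinder, optional bowel-fat specks) that share the SAT
# fat intensity but are labeled background - mirroring the manual removal
# of vertebral marrow from reference annotations and forcing the networks
# to learn spatial context rather than an intensity threshold.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Specify a synthetic Dixon abdominal phantom
#'
#' All parameters of the torso generator. Defaults reproduce the acquisition
#' geometry of the emulated protocol: a 192x192 matrix over a 400 mm
#' field of view (2.08 mm in-plane) with 51 axial slices of 5 mm.
#'
#' @param matrix_size Integer (nx, ny, nz), all >= 8.
#' @param voxel_size_mm Numeric (dx, dy, dz) in mm, all > 0.
#' @param torso_axes_mm Ellipse semi-axes (a, b) of the torso at the central
#'   slice; a mild quadratic taper (`torso_taper`) shrinks the profile
#'   towards the stack ends.
#' @param torso_taper Relative taper amplitude in \[0, 0.5\].
#' @param sat_thickness_mm Mean SAT ring thickness.
#' @param sat_modulation Relative angular/slice modulation amplitude of the
#'   ring thickness (0 gives a uniform annulus with a closed-form volume).
#' @param vat_fill_fraction Target fraction of eligible cavity voxels that
#'   are VAT, in \[0, 1\]; met exactly up to one voxel by construction.
#' @param n_vat_blobs Number of smooth random components whose superposition
#'   is thresholded to form VAT.
#' @param confounders Add the fat-bright vertebral marrow cylinder.
#' @param bowel_specks Number of small fat-bright non-VAT specks in the
#'   cavity (label 0, like the cylinder).
#' @param adiposity_score BMI-like covariate; scales the SAT ring thickness
#'   and the VAT fill fraction linearly (coefficient 1 around score 1).
#' @param age_like Covariate with no geometric effect (used for split
#'   stratification).
#' @param fat_signal,water_signal Mean channel intensities (a.u.).
#' @param noise_sigma Additive Gaussian noise scale per channel (magnitude
#'   images are clipped at zero).
#' @param include_ip Also synthesize the in-phase echo channel.
#' @param seed Default integer seed.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(192L, 192L, 51L),
                         voxel_size_mm = c(2.08, 2.08, 5),
                         torso_axes_mm = c(170, 125),
                         torso_taper = 0.05,
                         sat_thickness_mm = 20,
                         sat_modulation = 0.2,
                         vat_fill_fraction = 0.30,
                         n_vat_blobs = 8L,
                         confounders = TRUE,
                         bowel_specks = 2L,
                         adiposity_score = 1,
                         age_like = 50,
                         fat_signal = 200,
                         water_signal = 100,
                         noise_sigma = 8,
                         include_ip = FALSE,
                         seed = 1L) {
  spec <- structure(list(
    matrix_size = as.integer(matrix_size), voxel_size_mm = as.numeric(voxel_size_mm),
    torso_axes_mm = as.numeric(torso_axes_mm), torso_taper = torso_taper,
    sat_thickness_mm = sat_thickness_mm, sat_modulation = sat_modulation,
    vat_fill_fraction = vat_fill_fraction, n_vat_blobs = as.integer(n_vat_blobs),
    confounders = isTRUE(confounders), bowel_specks = as.integer(bowel_specks),
    adiposity_score = adiposity_score, age_like = age_like,
    fat_signal = fat_signal, water_signal = water_signal,
    noise_sigma = noise_sigma, include_ip = isTRUE(include_ip),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ms <- spec$matrix_size; vs <- spec$voxel_size_mm
  if (length(ms) != 3L || any(ms < 8L)) stop("matrix_size must be three extents >= 8")
  if (length(vs) != 3L || any(vs <= 0)) stop("voxel sizes must be > 0")
  if (spec$vat_fill_fraction < 0 || spec$vat_fill_fraction > 1) {
    stop("vat_fill_fraction must be in [0, 1]")
  }
  t_eff <- spec$sat_thickness_mm * spec$adiposity_score
  if (t_eff * (1 - spec$sat_modulation) < max(vs[1:2])) {
    stop("SAT ring thinner than one in-plane voxel: it would alias away")
  }
  fov <- ms[1:2] * vs[1:2]
  if (spec$torso_axes_mm[1] > fov[1] / 2 - 2 * vs[1] ||
      spec$torso_axes_mm[2] > fov[2] / 2 - 2 * vs[2]) {
    stop("torso ellipse must fit inside the FOV with a 2-voxel margin")
  }
  if (any(spec$torso_axes_mm - t_eff * (1 + spec$sat_modulation) <= 0)) {
    stop("SAT ring thickness exceeds the torso semi-axes")
  }
  invisible(spec)
}

# Anatomy that is shared between the two time points of one subject: torso
# profile parameters are deterministic from the spec; blob and speck
# placements are drawn here from the structure seed.
phantom_structure <- function(spec, structure_seed) {
  a0 <- spec$torso_axes_mm[1]; b0 <- spec$torso_axes_mm[2]
  with_seed(structure_seed, {
    k <- spec$n_vat_blobs
    blobs <- if (k > 0) data.frame(
      u = sqrt(stats::runif(k)), phi = stats::runif(k, 0, 2 * pi),
      cz = stats::runif(k, 0.1, 0.9),
      sx = stats::runif(k, 12, 35), sy = stats::runif(k, 12, 35),
      sz = stats::runif(k, 20, 60), amp = stats::runif(k, 0.6, 1)
    ) else NULL
    ns <- spec$bowel_specks
    specks <- if (spec$confounders && ns > 0) data.frame(
      u = sqrt(stats::runif(ns)), phi = stats::runif(ns, 0, 2 * pi),
      cz = stats::runif(ns, 0.15, 0.85), r = stats::runif(ns, 7, 12)
    ) else NULL
    list(blobs = blobs, specks = specks,
         vert_y = -0.45 * b0, vert_r = 0.12 * b0)
  })
}

# Render one time point: labels, channels, ground truth.
phantom_render <- function(spec, struct, noise_seed) {
  ms <- spec$matrix_size; vs <- spec$voxel_size_mm
  nx <- ms[1]; ny <- ms[2]; nz <- ms[3]
  dx <- vs[1]; dy <- vs[2]; dz <- vs[3]
  t_eff <- spec$sat_thickness_mm * spec$adiposity_score
  fill_eff <- min(max(spec$vat_fill_fraction * spec$adiposity_score, 0), 1)

  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  yc <- (seq_len(ny) - (ny + 1) / 2) * dy
  zc <- (seq_len(nz) - 0.5) * dz
  zext <- nz * dz
  zrel <- (zc - zext / 2) / (zext / 2)          # in [-1, 1]
  sz_scale <- 1 - spec$torso_taper * zrel^2
  Xg <- matrix(xc, nx, ny)
  Yg <- matrix(yc, nx, ny, byrow = TRUE)
  theta <- atan2(Yg, Xg)

  labels <- array(0L, ms)
  cavity <- array(FALSE, ms)
  conf <- array(FALSE, ms)
  analytic_sat <- 0
  a_z <- spec$torso_axes_mm[1] * sz_scale
  b_z <- spec$torso_axes_mm[2] * sz_scale
  for (iz in seq_len(nz)) {
    a <- a_z[iz]; b <- b_z[iz]
    tt <- t_eff * (1 + spec$sat_modulation * sin(2 * theta + 2 * pi * iz / nz))
    rho_out <- sqrt((Xg / a)^2 + (Yg / b)^2)
    rho_in <- sqrt((Xg / (a - tt))^2 + (Yg / (b - tt))^2)
    torso <- rho_out <= 1
    sl <- matrix(0L, nx, ny)
    sl[torso & rho_in > 1] <- 1L
    labels[, , iz] <- sl
    cavity[, , iz] <- rho_in <= 1
    analytic_sat <- analytic_sat + pi * (a * b - (a - t_eff) * (b - t_eff)) * dz
  }

  # fat-bright confounders, labeled background
  if (spec$confounders) {
    cyl <- outer((Xg - 0)^2 + (Yg - struct$vert_y)^2 <= struct$vert_r^2,
                 rep(TRUE, nz))
    conf <- conf | (cyl & cavity)
    if (!is.null(struct$specks)) {
      for (i in seq_len(nrow(struct$specks))) {
        s <- struct$specks[i, ]
        scx <- s$u * cos(s$phi) * 0.6 * (spec$torso_axes_mm[1] - t_eff)
        scy <- s$u * sin(s$phi) * 0.6 * (spec$torso_axes_mm[2] - t_eff)
        scz <- s$cz * zext
        d2 <- outer((Xg - scx)^2 + (Yg - scy)^2, (zc - scz)^2, `+`)
        conf <- conf | (array(d2, ms) <= s$r^2 & cavity)
      }
    }
  }

  # VAT: threshold the blob superposition over eligible cavity voxels so
  # the fill fraction is met exactly (up to one voxel)
  free <- cavity & !conf
  idx <- which(free)
  if (fill_eff > 0 && length(idx) > 0 && !is.null(struct$blobs)) {
    co <- arrayInd(idx, ms)
    px <- xc[co[, 1]]; py <- yc[co[, 2]]; pz <- zc[co[, 3]]
    field <- numeric(length(idx))
    for (i in seq_len(nrow(struct$blobs))) {
      bl <- struct$blobs[i, ]
      cx <- bl$u * cos(bl$phi) * 0.7 * (spec$torso_axes_mm[1] - t_eff)
      cy <- bl$u * sin(bl$phi) * 0.7 * (spec$torso_axes_mm[2] - t_eff)
      czm <- bl$cz * zext
      field <- field + bl$amp * exp(-0.5 * (((px - cx) / bl$sx)^2 +
                                            ((py - cy) / bl$sy)^2 +
                                            ((pz - czm) / bl$sz)^2))
    }
    k_target <- round(fill_eff * length(idx))
    if (k_target > 0) {
      thr <- sort(field, decreasing = TRUE)[k_target]
      labels[idx[field >= thr]] <- 2L
    }
  }

  # signal model: binary fat/water maps, independent Gaussian noise per
  # channel, clipped at zero (magnitude approximation)
  adipose <- labels == 1L | labels == 2L | conf
  lean <- cavity & !adipose
  f <- spec$fat_signal * adipose
  w <- spec$water_signal * lean
  ch <- with_seed(noise_seed, {
    ns <- spec$noise_sigma
    n <- prod(ms)
    mk <- function(base) {
      v <- base + if (ns > 0) array(stats::rnorm(n, sd = ns), ms) else 0
      v[v < 0] <- 0
      if (!is.array(v)) v <- array(v, ms)
      v
    }
    out <- list(op = mk(abs(w - f)), water = mk(w), fat = mk(f))
    if (spec$include_ip) out$ip <- mk(w + f)
    out[c("op", "water", "fat", if (spec$include_ip) "ip")]
  })

  voxvol <- dx * dy * dz
  list(labels = labels, channels = ch,
       sat_volume_mL = sum(labels == 1L) * voxvol / 1000,
       vat_volume_mL = sum(labels == 2L) * voxvol / 1000,
       analytic_sat_volume_mL = analytic_sat / 1000)
}

#' Generate one synthetic Dixon subject
#'
#' Deterministic in (spec, seed): the same call reproduces bit-identical
#' channels and masks.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param subject_id,timepoint Recorded identity.
#' @return List with `volume` ([multi_contrast_volume()]), `mask`
#'   ([seg_mask()]) and `truth` (voxel-count and closed-form SAT/VAT volumes
#'   in mL plus the covariates).
#' @export
generate_subject <- function(spec, seed = spec$seed, subject_id = "subject",
                             timepoint = 1L) {
  validate_phantom_spec(spec)
  struct <- phantom_structure(spec, structure_seed = seed)
  r <- phantom_render(spec, struct, noise_seed = derive_seed(seed, timepoint))
  vol <- multi_contrast_volume(r$channels, spec$voxel_size_mm,
                               subject_id = subject_id, timepoint = timepoint)
  mask <- seg_mask(r$labels, spec$voxel_size_mm,
                   subject_id = subject_id, timepoint = timepoint)
  truth <- list(sat_volume_mL = r$sat_volume_mL, vat_volume_mL = r$vat_volume_mL,
                analytic_sat_volume_mL = r$analytic_sat_volume_mL,
                covariates = list(adiposity_score = spec$adiposity_score,
                                  age_like = spec$age_like))
  list(volume = vol, mask = mask, truth = truth)
}

#' Generate a longitudinal phantom pair
#'
#' Time point 2 re-renders the same anatomy (identical torso profile, blob
#' and confounder placement) with the SAT ring thickness scaled by
#' `1 + delta[1]` and the VAT fill fraction by `1 + delta[2]`, plus
#' independent noise, so the pair depicts one subject whose adipose
#' compartments changed by a controlled amount.
#'
#' @inheritParams generate_subject
#' @param delta Numeric (d_sat_frac, d_vat_frac), each in (-0.9, 0.9).
#' @return List with elements `tp1` and `tp2` (each as
#'   [generate_subject()]) and `true_delta_mL`, the recorded
#'   `Volume2 - Volume1` per tissue.
#' @export
generate_longitudinal_pair <- function(spec, delta = c(0, 0), seed = spec$seed,
                                       subject_id = "subject") {
  if (any(delta <= -0.9) || any(delta >= 0.9)) {
    stop("delta fractions must lie in (-0.9, 0.9)")
  }
  spec2 <- spec
  spec2$sat_thickness_mm <- spec$sat_thickness_mm * (1 + delta[1])
  spec2$vat_fill_fraction <- min(max(spec$vat_fill_fraction * (1 + delta[2]), 0), 1)
  validate_phantom_spec(spec)
  validate_phantom_spec(spec2)
  struct <- phantom_structure(spec, structure_seed = seed)
  r1 <- phantom_render(spec, struct, noise_seed = derive_seed(seed, 1L))
  r2 <- phantom_render(spec2, struct, noise_seed = derive_seed(seed, 2L))
  pack <- function(r, sp, tp) {
    list(volume = multi_contrast_volume(r$channels, sp$voxel_size_mm,
                                        subject_id = subject_id, timepoint = tp),
         mask = seg_mask(r$labels, sp$voxel_size_mm,
                         subject_id = subject_id, timepoint = tp),
         truth = list(sat_volume_mL = r$sat_volume_mL,
                      vat_volume_mL = r$vat_volume_mL,
                      analytic_sat_volume_mL = r$analytic_sat_volume_mL,
                      covariates = list(adiposity_score = sp$adiposity_score,
                                        age_like = sp$age_like)))
  }
  t1 <- pack(r1, spec, 1L); t2 <- pack(r2, spec2, 2L)
  list(tp1 = t1, tp2 = t2,
       true_delta_mL = c(sat = t2$truth$sat_volume_mL - t1$truth$sat_volume_mL,
                         vat = t2$truth$vat_volume_mL - t1$truth$vat_volume_mL))
}

#' Generate a longitudinal phantom cohort
#'
#' Samples per-subject covariates (adiposity score and an age-like
#' covariate), renders both time points of every subject, optionally writes
#' all volumes and masks as NIfTI through the volume IO layer, and returns
#' a cohort manifest with one row per (subject, timepoint).
#'
#' @param n Number of subjects (>= 1).
#' @param spec Base [phantom_spec()]; per-subject specs modify its
#'   covariates.
#' @param out_dir Output directory for NIfTI files and the manifest CSV;
#'   `NULL` keeps the cohort in memory only.
#' @param adiposity Mean and sd of the Gaussian adiposity-score sampler.
#' @param age Mean and sd of the Gaussian age-like sampler.
#' @param delta_range Uniform range for the per-subject longitudinal volume
#'   change fractions (applied independently to SAT and VAT).
#' @param seed Cohort seed.
#' @param keep_data Return the rendered volumes/masks in memory (default
#'   when not writing to disk).
#' @return A `data.frame` manifest (invisibly carries the in-memory data as
#'   attribute `"data"` when `keep_data`).
#' @export
generate_cohort <- function(n, spec = phantom_spec(), out_dir = NULL,
                            adiposity = c(mean = 1, sd = 0.15),
                            age = c(mean = 50, sd = 14),
                            delta_range = c(-0.15, 0.15),
                            seed = 1L, keep_data = is.null(out_dir)) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  cov <- with_seed(seed, data.frame(
    adiposity_score = stats::rnorm(n, adiposity[["mean"]], adiposity[["sd"]]),
    age_like = stats::rnorm(n, age[["mean"]], age[["sd"]]),
    d_sat = stats::runif(n, delta_range[1], delta_range[2]),
    d_vat = stats::runif(n, delta_range[1], delta_range[2])
  ))
  cov$adiposity_score <- pmin(pmax(cov$adiposity_score, 0.6), 1.6)
  rows <- list()
  data <- if (keep_data) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sid <- sprintf("phantom%03d", i)
    sp <- spec
    sp$adiposity_score <- cov$adiposity_score[i]
    sp$age_like <- cov$age_like[i]
    pair <- generate_longitudinal_pair(sp, delta = c(cov$d_sat[i], cov$d_vat[i]),
                                       seed = derive_seed(seed, i), subject_id = sid)
    if (keep_data) data[[i]] <- pair
    for (tp in 1:2) {
      el <- if (tp == 1L) pair$tp1 else pair$tp2
      paths <- rep(NA_character_, 4L)
      names(paths) <- c("op", "water", "fat", "mask")
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_tp%d", sid, tp))
        wr <- write_subject(el$volume, el$mask, stem)
        paths[c("op", "water", "fat")] <- wr$channels[c("op", "water", "fat")]
        paths["mask"] <- wr$mask
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, timepoint = tp,
        path_op = paths[["op"]], path_water = paths[["water"]],
        path_fat = paths[["fat"]], path_mask = paths[["mask"]],
        adiposity_score = cov$adiposity_score[i], age_like = cov$age_like[i],
        true_sat_mL = el$truth$sat_volume_mL, true_vat_mL = el$truth$vat_volume_mL,
        landmark_index = 1L, split = "none", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  if (keep_data) attr(manifest, "data") <- data
  manifest
}
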