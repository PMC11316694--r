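# Per-subject segmentation metrics, volume quantification, agreement
# statistics, and the nonparametric group-comparison layer.

#' 3D Dice score for one class
#'
#' `2|P intersect R| / (|P| + |R|)` over the whole volume for the given
#' label. When the class is empty in both masks the score is defined as 1
#' (perfect agreement on absence) and a message is logged.
#'
#' @param pred,ref [seg_mask()] objects (or plain label arrays) on the same
#'   grid.
#' @param class_label Integer label (1 SAT, 2 VAT).
#' @return Dice score in \[0, 1\].
#' @export
dice3d <- function(pred, ref, class_label) {
  if (!same_grid(pred, ref)) stop("prediction and reference grids differ")
  p <- mask_indicator(pred, class_label)
  r <- mask_indicator(ref, class_label)
  np <- sum(p); nr <- sum(r)
  if (np + nr == 0) {
    message("dice3d: class ", class_label, " empty in both masks; returning 1")
    return(1)
  }
  2 * sum(p & r) / (np + nr)
}

#' Pooled false-positive and false-negative rates
#'
#' FP is the percentage of reference-negative voxels predicted positive and
#' FN the percentage of reference-positive voxels predicted negative, with
#' the SAT and VAT classes pooled in both numerator and denominator: the
#' class-wise indicators are the one-hot channels of the 3-label mask, so a
#' SAT voxel predicted as VAT contributes to SAT's FN and VAT's FP.
#'
#' Instead of label masks, `pred` and `ref` may each be a list with
#' logical/0-1 elements `sat` and `vat` holding the per-class indicators
#' `p_ln` / `r_ln` directly (the one-hot channels need not be exclusive in
#' that form).
#'
#' @inheritParams dice3d
#' @return Named numeric `c(fp_pct, fn_pct)`, each in \[0, 100\].
#' @export
fp_fn_rates <- function(pred, ref) {
  ind <- function(obj, cl) {
    if (is.list(obj) && !inherits(obj, "seg_mask")) {
      obj[[c("sat", "vat")[cl]]] > 0
    } else {
      mask_indicator(obj, cl)
    }
  }
  if (!is.list(pred) || inherits(pred, "seg_mask")) {
    if (!same_grid(pred, ref)) stop("prediction and reference grids differ")
  }
  fp_num <- 0; fp_den <- 0; fn_num <- 0; fn_den <- 0
  for (cl in 1:2) {
    p <- ind(pred, cl)
    r <- ind(ref, cl)
    if (length(p) != length(r)) stop("prediction and reference grids differ")
    fp_num <- fp_num + sum(!r & p)
    fp_den <- fp_den + sum(!r)
    fn_num <- fn_num + sum(r & !p)
    fn_den <- fn_den + sum(r)
  }
  fp <- if (fp_den == 0) { warning("no reference-negative voxels; FP defined as 0"); 0 }
        else 100 * fp_num / fp_den
  fn <- if (fn_den == 0) { warning("no reference-positive voxels; FN defined as 0"); 0 }
        else 100 * fn_num / fn_den
  c(fp_pct = fp, fn_pct = fn)
}

#' Mask volume in millilitres
#'
#' Voxel count times the voxel volume: `count * dx * dy * dz / 1000`.
#'
#' @param mask A [seg_mask()] (or label array, in which case
#'   `voxel_size_mm` is required).
#' @param class_label Integer label.
#' @param voxel_size_mm Voxel spacing override.
#' @return Volume in mL.
#' @export
mask_volume <- function(mask, class_label, voxel_size_mm = NULL) {
  vs <- voxel_size_mm %||% (if (inherits(mask, "seg_mask")) mask$voxel_size_mm)
  if (is.null(vs) || any(vs <= 0)) stop("positive voxel sizes required")
  sum(mask_indicator(mask, class_label)) * prod(vs) / 1000
}

#' Intraclass correlation agreement between two volume series
#'
#' Default variant: two-way model, absolute agreement, single measurement
#' (ICC(A,1)), computed from the ANOVA mean squares; absolute agreement is
#' used because measurement bias matters for volume quantification. The
#' qualitative category uses the conventional cutpoints: poor < 0.5,
#' moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9. Also reports the
#' linear regression of `b` on `a`.
#'
#' @param a,b Numeric series of equal length >= 3 (e.g. reference and
#'   predicted volumes).
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @return An `agreement_result`: `icc`, `category`, `slope`, `intercept`,
#'   `n`, `type`.
#' @export
icc_agreement <- function(a, b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b), length(a) >= 3)
  n <- length(a); k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    icc <- if (all(a == b)) 1 else NA_real_
  } else if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
  }
  category <- if (is.na(icc)) NA_character_
  else if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
  fit <- if (stats::var(a) > 0) stats::lm(b ~ a) else NULL
  structure(list(icc = icc, category = category,
                 slope = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[2]),
                 intercept = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[1]),
                 n = n, type = type),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.4f (%s); regression b = %.3f a + %.2f (n = %d)\n",
              if (x$type == "agreement") "A" else "C",
              x$icc, x$category, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Longitudinal volume-change regression
#'
#' `DeltaVolume = Volume(tp2) - Volume(tp1)` per subject and tissue, for
#' both the predicted and the reference volumes, with the regression of
#' predicted on reference change reported per tissue.
#'
#' @param t1,t2 Data frames with columns `subject_id`, `ref_sat_mL`,
#'   `ref_vat_mL`, `pred_sat_mL`, `pred_vat_mL` at time points 1 and 2.
#' @return List with per-subject deltas and per-tissue slope/intercept.
#' @export
delta_volume_analysis <- function(t1, t2) {
  miss1 <- setdiff(t2$subject_id, t1$subject_id)
  miss2 <- setdiff(t1$subject_id, t2$subject_id)
  if (length(miss1) || length(miss2)) {
    stop("unmatched subjects across time points: ",
         paste(unique(c(miss1, miss2)), collapse = ", "))
  }
  t2 <- t2[match(t1$subject_id, t2$subject_id), ]
  out <- list(subjects = t1$subject_id)
  for (tis in c("sat", "vat")) {
    dref <- t2[[paste0("ref_", tis, "_mL")]] - t1[[paste0("ref_", tis, "_mL")]]
    dpred <- t2[[paste0("pred_", tis, "_mL")]] - t1[[paste0("pred_", tis, "_mL")]]
    if (stats::var(dref) == 0) {
      sl <- if (all(dpred == dref)) 1 else NA_real_
      ic <- if (all(dpred == dref)) 0 else NA_real_
    } else {
      fit <- stats::lm(dpred ~ dref)
      sl <- unname(stats::coef(fit)[2]); ic <- unname(stats::coef(fit)[1])
    }
    out[[paste0("delta_", tis)]] <- data.frame(
      subject_id = t1$subject_id, ref_delta_mL = dref, pred_delta_mL = dpred)
    out[[paste0(tis, "_slope")]] <- sl
    out[[paste0(tis, "_intercept")]] <- ic
  }
  out
}

#' Nonparametric group and paired comparisons
#'
#' Thin, consistently-shaped wrappers over the standard rank tests:
#' Kruskal-Wallis across groups (tie-corrected) and the Wilcoxon
#' signed-rank test for paired series. Zero paired differences are
#' discarded (classic Wilcoxon rule); if all differences are zero the
#' result is "no difference" with p = 1. The exact distribution is used for
#' up to 25 nonzero pairs without ties, the normal approximation with
#' continuity correction otherwise.
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return `kruskal_wallis`: list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' @rdname kruskal_wallis
#' @param a,b Paired numeric vectors of equal length.
#' @return `wilcoxon_signed_rank`: list with `V`, `p` and `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(V = 0, p = 1, n_nonzero = 0L))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value, n_nonzero = length(nz))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Controls the false discovery rate at level `q`: sort p-values
#' ascending and reject all hypotheses up to the largest `i` with
#' `p(i) <= i q / m`. Adjusted p-values are the standard BH values
#' (monotone in the raw p-value ranks).
#'
#' @param p Numeric vector of raw p-values.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` (same order as `p`), `reject` (logical) and
#'   `n_rejected`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  adj <- stats::p.adjust(p, method = "BH")
  o <- order(p)
  thr <- seq_len(m) * q / m
  ok <- which(p[o] <= thr)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  list(adjusted = adj, reject = reject, n_rejected = sum(reject))
}

#' Summarize per-subject metrics across a cohort
#'
#' Medians and interquartile ranges (linear-interpolation quantiles) of the
#' per-subject scores, plus volume agreement (ICC and regression) per
#' tissue.
#'
#' @param per_subject Data frame as returned by [evaluate_cohort()].
#' @return List with `medians`, `iqrs`, and per-tissue `agreement_result`s.
#' @export
summarize_metrics <- function(per_subject) {
  cols <- c("dice_sat", "dice_vat", "fp_pct", "fn_pct")
  med <- vapply(cols, function(cc) stats::median(per_subject[[cc]]), 0)
  iqr <- vapply(cols, function(cc) {
    q <- stats::quantile(per_subject[[cc]], c(0.25, 0.75), type = 7)
    unname(q[2] - q[1])
  }, 0)
  list(medians = med, iqrs = iqr,
       icc_sat = icc_agreement(per_subject$ref_sat_mL, per_subject$pred_sat_mL),
       icc_vat = icc_agreement(per_subject$ref_vat_mL, per_subject$pred_vat_mL))
}
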