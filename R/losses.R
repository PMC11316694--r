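#' Configure a segmentation loss
#'
#' Two imbalance-aware soft Dice losses over the 3-class probability map:
#' the weighted Dice loss (`WDL`), a convex combination of per-class soft
#' Dice terms, and the frequency-balancing boundary-emphasizing Dice loss
#' (`FBDL`), which sets the class weights inversely proportional to the
#' reference class frequencies and up-weights voxels within a band around
#' the reference label boundaries. FBDL targets the spatial complexity of
#' VAT and the strong class imbalance between SAT and VAT.
#'
#' @param type `"WDL"` or `"FBDL"`.
#' @param class_weight_mode How FBDL derives class weights:
#'   `"inverse_frequency_dataset"` (from frequencies supplied by the
#'   trainer over the whole training set; stable), `"inverse_frequency_batch"`
#'   (from the reference at hand) or `"manual"`.
#' @param class_weights Manual weights (normalized internally to sum 1);
#'   for WDL the default is uniform over the included classes.
#' @param boundary_band_voxels Band half-width d around reference label
#'   boundaries (6-connected morphological gradient dilated to width d).
#' @param boundary_multiplier Voxel weight beta >= 1 inside the band.
#' @param smoothing Additive smoothing epsilon in numerator and denominator.
#' @param include_background Include the background class in the Dice sum
#'   (default TRUE, so false positives on background stay penalized).
#' @return A `loss_config` list.
#' @export
loss_config <- function(type = c("WDL", "FBDL"),
                        class_weight_mode = c("inverse_frequency_dataset",
                                              "inverse_frequency_batch", "manual"),
                        class_weights = NULL,
                        boundary_band_voxels = 1L,
                        boundary_multiplier = 2,
                        smoothing = 1e-5,
                        include_background = TRUE) {
  type <- match.arg(type)
  class_weight_mode <- match.arg(class_weight_mode)
  if (!is.null(class_weights)) {
    if (any(class_weights < 0) || sum(class_weights) == 0) {
      stop("class_weights must be non-negative and sum to a positive value")
    }
    class_weights <- class_weights / sum(class_weights)
  }
  stopifnot(boundary_multiplier >= 1, boundary_band_voxels >= 1)
  structure(list(type = type, class_weight_mode = class_weight_mode,
                 class_weights = class_weights,
                 boundary_band_voxels = as.integer(boundary_band_voxels),
                 boundary_multiplier = boundary_multiplier,
                 smoothing = smoothing,
                 include_background = isTRUE(include_background)),
            class = "loss_config")
}

# Voxels adjacent (6-connectivity) to a label change; both sides of the
# interface are marked, matching a morphological gradient of the one-hot
# reference. `d` > 1 dilates the band with the same structuring element.
boundary_band <- function(lab, d = 1L) {
  dims <- dim(lab)
  b <- array(FALSE, dims)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  if (n1 > 1L) {
    df <- lab[-1, , , drop = FALSE] != lab[-n1, , , drop = FALSE]
    b[-1, , ] <- b[-1, , , drop = FALSE] | df
    b[-n1, , ] <- b[-n1, , , drop = FALSE] | df
  }
  if (n2 > 1L) {
    df <- lab[, -1, , drop = FALSE] != lab[, -n2, , drop = FALSE]
    b[, -1, ] <- b[, -1, , drop = FALSE] | df
    b[, -n2, ] <- b[, -n2, , drop = FALSE] | df
  }
  if (n3 > 1L) {
    df <- lab[, , -1, drop = FALSE] != lab[, , -n3, drop = FALSE]
    b[, , -1] <- b[, , -1, drop = FALSE] | df
    b[, , -n3] <- b[, , -n3, drop = FALSE] | df
  }
  while (d > 1L) {
    g <- b
    if (n1 > 1L) { g[-1, , ] <- g[-1, , , drop = FALSE] | b[-n1, , , drop = FALSE]
                   g[-n1, , ] <- g[-n1, , , drop = FALSE] | b[-1, , , drop = FALSE] }
    if (n2 > 1L) { g[, -1, ] <- g[, -1, , drop = FALSE] | b[, -n2, , drop = FALSE]
                   g[, -n2, ] <- g[, -n2, , drop = FALSE] | b[, -1, , drop = FALSE] }
    if (n3 > 1L) { g[, , -1] <- g[, , -1, drop = FALSE] | b[, , -n3, drop = FALSE]
                   g[, , -n3] <- g[, , -n3, drop = FALSE] | b[, , -1, drop = FALSE] }
    b <- g
    d <- d - 1L
  }
  b
}

# Core weighted soft Dice: per class l,
#   D_l = (2 sum_n m_n p_ln r_ln + eps) / (sum_n m_n p_ln + sum_n m_n r_ln + eps)
# loss = 1 - sum_l w_l D_l. Returns the loss and, if grad, dLoss/dprobs.
soft_dice_eval <- function(probs, lab, classes, w, m, eps, grad = FALSE) {
  d <- dim(probs)
  nvox <- prod(d[1:3])
  P <- matrix(probs, nvox, d[4])
  mv <- if (length(m) == 1L) NULL else as.vector(m)
  loss <- 1
  G <- if (grad) matrix(0, nvox, d[4]) else NULL
  for (j in seq_along(classes)) {
    cl <- classes[j]
    r <- as.numeric(as.vector(lab) == cl)
    p <- P[, cl + 1L]
    if (is.null(mv)) {
      num <- 2 * sum(p * r) + eps
      den <- sum(p) + sum(r) + eps
    } else {
      num <- 2 * sum(mv * p * r) + eps
      den <- sum(mv * p) + sum(mv * r) + eps
    }
    loss <- loss - w[j] * num / den
    if (grad) {
      mm <- if (is.null(mv)) 1 else mv
      G[, cl + 1L] <- G[, cl + 1L] - w[j] * mm * (2 * r * den - num) / den^2
    }
  }
  if (grad) { dim(G) <- d; list(loss = loss, dprobs = G) } else list(loss = loss)
}

resolve_loss_weights <- function(cfg, lab, n_classes, dataset_freqs = NULL) {
  classes <- if (cfg$include_background) 0:(n_classes - 1L) else 1:(n_classes - 1L)
  if (cfg$type == "WDL" || cfg$class_weight_mode == "manual") {
    w <- cfg$class_weights %||% rep(1 / length(classes), length(classes))
    if (length(w) != length(classes)) stop("class_weights length must match included classes")
    return(list(classes = classes, w = w / sum(w)))
  }
  freqs <- if (cfg$class_weight_mode == "inverse_frequency_dataset" && !is.null(dataset_freqs)) {
    dataset_freqs[classes + 1L]
  } else {
    n <- length(lab)
    vapply(classes, function(cl) sum(lab == cl) / n, 0)
  }
  # absent-class fallback: floor of one voxel equivalent, never divide by 0
  floorf <- 1 / max(length(lab), 1L)
  w <- 1 / pmax(freqs, floorf)
  list(classes = classes, w = w / sum(w))
}

loss_eval <- function(probs, ref, cfg, dataset_freqs = NULL, grad = FALSE) {
  lab <- if (inherits(ref, "seg_mask")) ref$labels else ref
  d <- dim(probs)
  if (!identical(d[1:3], dim(lab))) {
    stop(sprintf("probability map grid (%s) does not match reference grid (%s)",
                 paste(d[1:3], collapse = "x"), paste(dim(lab), collapse = "x")))
  }
  rw <- resolve_loss_weights(cfg, lab, d[4], dataset_freqs)
  m <- if (cfg$type == "FBDL" && cfg$boundary_multiplier > 1) {
    1 + (cfg$boundary_multiplier - 1) * boundary_band(lab, cfg$boundary_band_voxels)
  } else 1
  res <- soft_dice_eval(probs, lab, rw$classes, rw$w, m, cfg$smoothing, grad = grad)
  res$weights <- rw$w
  res$classes <- rw$classes
  res
}

#' Weighted Dice loss
#'
#' `1 - sum_l w_l D_l` over soft per-class Dice scores `D_l`, with weights
#' normalized to sum 1 (uniform over the included classes by default).
#'
#' @param probs 4D array (x, y, z, class) of per-voxel class probabilities.
#' @param ref Reference [seg_mask()] (or a plain integer label array) on the
#'   same grid.
#' @param cfg A [loss_config()].
#' @return Scalar loss in \[0, 1\].
#' @export
weighted_dice_loss <- function(probs, ref, cfg = loss_config("WDL")) {
  loss_eval(probs, ref, cfg, grad = FALSE)$loss
}

#' Frequency-balancing boundary-emphasizing Dice loss
#'
#' Weighted soft Dice with class weights proportional to inverse reference
#' class frequency and voxel weights `m_n = 1 + (beta - 1)` inside a band of
#' width `d` around the reference label boundaries; `m_n` enters all three
#' Dice sums. With `beta = 1` and equal class frequencies it reduces to the
#' uniform weighted Dice loss.
#'
#' @inheritParams weighted_dice_loss
#' @param dataset_freqs Optional length-3 class frequency vector computed
#'   over the training set (used with the
#'   `"inverse_frequency_dataset"` weight mode).
#' @return Scalar loss in \[0, 1\].
#' @export
fbdl <- function(probs, ref, cfg = loss_config("FBDL"), dataset_freqs = NULL) {
  if (cfg$type != "FBDL") cfg$type <- "FBDL"
  loss_eval(probs, ref, cfg, dataset_freqs = dataset_freqs, grad = FALSE)$loss
}

# Chain rule through the softmax head: given dL/dP and P = softmax(z),
# dL/dz = P * (g - rowSums(g * P)).
dlogits_from_dprobs <- function(P, G) {
  d <- dim(P)
  Pm <- matrix(P, prod(d[1:3]), d[4])
  Gm <- matrix(G, prod(d[1:3]), d[4])
  s <- rowSums(Gm * Pm)
  out <- Pm * (Gm - s)
  dim(out) <- d
  out
}
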