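#' Multi-contrast Dixon volume
#'
#' Co-registered 3D magnitude images from a two-point Dixon acquisition:
#' opposed-phase (`op`), water (`water`) and fat (`fat`), optionally the
#' in-phase echo (`ip`). All channels share one grid and one affine; the
#' channel order is fixed and recorded.
#'
#' @param channels Named list of 3D arrays; names from
#'   `c("op", "water", "fat", "ip")` in that order.
#' @param voxel_size_mm Numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @param affine 4x4 grid-to-world transform; default is a diagonal RAS+
#'   scaling by the voxel size.
#' @param subject_id,timepoint Identity of the scan; timepoint is 1 or 2.
#' @return An object of class `mc_volume`.
#' @export
multi_contrast_volume <- function(channels, voxel_size_mm,
                                  affine = NULL, subject_id = "subject",
                                  timepoint = 1L) {
  order <- c("op", "water", "fat", "ip")
  if (is.null(names(channels)) || !all(names(channels) %in% order)) {
    stop("channels must be named with: ", paste(order, collapse = ", "))
  }
  channels <- channels[order[order %in% names(channels)]]
  d <- dim(channels[[1]])
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), d)) {
      stop(sprintf("channel '%s' has shape (%s) but '%s' has (%s)",
                   nm, paste(dim(channels[[nm]]), collapse = "x"),
                   names(channels)[1], paste(d, collapse = "x")))
    }
    if (any(channels[[nm]] < 0)) stop("magnitude channels must be non-negative")
  }
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(channels = channels, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine, subject_id = as.character(subject_id),
                 timepoint = as.integer(timepoint)),
            class = "mc_volume")
}

#' Three-label segmentation mask
#'
#' Integer labels on the acquisition grid: 0 background, 1 subcutaneous
#' adipose tissue (SAT), 2 visceral adipose tissue (VAT). Labels are
#' mutually exclusive by construction.
#'
#' @param labels 3D integer array over \{0, 1, 2\}.
#' @inheritParams multi_contrast_volume
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, voxel_size_mm, affine = NULL,
                     subject_id = "subject", timepoint = 1L) {
  if (!all(labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  stopifnot(length(dim(labels)) == 3L, length(voxel_size_mm) == 3L,
            all(voxel_size_mm > 0))
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(list(labels = labels, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine, subject_id = as.character(subject_id),
                 timepoint = as.integer(timepoint)),
            class = "seg_mask")
}

#' @export
print.mc_volume <- function(x, ...) {
  cat(sprintf("<mc_volume> %s (tp %d): %s | %s voxels @ %.2fx%.2fx%.2f mm\n",
              x$subject_id, x$timepoint, paste(names(x$channels), collapse = "+"),
              paste(dim(x$channels[[1]]), collapse = "x"),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 3L)
  cat(sprintf("<seg_mask> %s (tp %d): %s voxels | bg %d, SAT %d, VAT %d\n",
              x$subject_id, x$timepoint, paste(dim(x$labels), collapse = "x"),
              tab[1], tab[2], tab[3]))
  invisible(x)
}

# One-hot reference indicators r_ln for a label: 1 where the mask equals
# the class, 0 elsewhere.
mask_indicator <- function(mask, class_label) {
  lab <- if (inherits(mask, "seg_mask")) mask$labels else mask
  lab == class_label
}

same_grid <- function(a, b) {
  da <- if (inherits(a, "seg_mask")) dim(a$labels) else dim(a)
  db <- if (inherits(b, "seg_mask")) dim(b$labels) else dim(b)
  identical(da, db)
}
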