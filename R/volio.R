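# Volume/mask IO (NIfTI via RNifti), cohort manifests, and the
# landmark-based slice-selection rule. Slice indices are 1-based and slice
# ranges are inclusive-inclusive throughout.

strip_nifti_attrs <- function(arr) {
  d <- dim(arr)
  attributes(arr) <- list(dim = d)
  arr
}

nifti_from_array <- function(arr, voxel_size_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  img
}

#' Write / read one subject's volumes and mask
#'
#' One NIfTI file per channel (suffixes `_op`, `_water`, `_fat`, optionally
#' `_ip`) plus a `_mask` NIfTI with integer labels \{0, 1, 2\}. The affine
#' encodes the voxel size (RAS+, superior = increasing slice index).
#'
#' @param vol A [multi_contrast_volume()].
#' @param mask A [seg_mask()] on the same grid.
#' @param stem Output path prefix.
#' @return `write_subject`: list with the written channel paths and mask
#'   path. `read_subject`: list with `volume` and `mask`.
#' @export
write_subject <- function(vol, mask, stem) {
  stopifnot(inherits(vol, "mc_volume"), inherits(mask, "seg_mask"))
  if (!identical(dim(vol$channels[[1]]), dim(mask$labels))) {
    stop("volume and mask grids differ")
  }
  paths <- character(0)
  for (nm in names(vol$channels)) {
    p <- paste0(stem, "_", nm, ".nii.gz")
    RNifti::writeNifti(nifti_from_array(vol$channels[[nm]], vol$voxel_size_mm), p,
                       datatype = "float")
    paths[nm] <- p
  }
  mp <- paste0(stem, "_mask.nii.gz")
  RNifti::writeNifti(nifti_from_array(mask$labels, mask$voxel_size_mm), mp,
                     datatype = "int16")
  list(channels = paths, mask = mp)
}

#' @rdname write_subject
#' @param subject_id,timepoint Identity to record on the read objects.
#' @export
read_subject <- function(stem, subject_id = basename(stem), timepoint = 1L) {
  chn <- c("op", "water", "fat", "ip")
  paths <- paste0(stem, "_", chn, ".nii.gz")
  names(paths) <- chn
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) stop("no channel files found for stem: ", stem)
  vol <- read_volume(paths, subject_id = subject_id, timepoint = timepoint)
  mp <- paste0(stem, "_mask.nii.gz")
  mask <- if (file.exists(mp)) read_mask(mp, subject_id = subject_id, timepoint = timepoint)
  list(volume = vol, mask = mask)
}

#' Read a multi-contrast volume from per-channel NIfTI files
#'
#' All channels must share shape and voxel geometry; a mismatch is a hard
#' error naming the offending file and both shapes.
#'
#' @param paths Named character vector of NIfTI paths; names from
#'   `c("op", "water", "fat", "ip")`.
#' @param subject_id,timepoint Identity to record.
#' @return A [multi_contrast_volume()].
#' @export
read_volume <- function(paths, subject_id = "subject", timepoint = 1L) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  channels <- list()
  ref_dim <- NULL; ref_vox <- NULL; ref_path <- NULL
  for (nm in names(paths)) {
    img <- RNifti::readNifti(paths[[nm]])
    arr <- strip_nifti_attrs(as.array(img))
    vox <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(arr))))]
    if (is.null(ref_dim)) {
      ref_dim <- dim(arr); ref_vox <- vox; ref_path <- paths[[nm]]
    } else if (!identical(dim(arr), ref_dim)) {
      stop(sprintf("channel file '%s' has shape (%s) but '%s' has (%s)",
                   paths[[nm]], paste(dim(arr), collapse = "x"),
                   ref_path, paste(ref_dim, collapse = "x")))
    } else if (max(abs(vox - ref_vox)) > 1e-4) {
      stop(sprintf("channel file '%s' voxel size (%s) differs from '%s' (%s)",
                   paths[[nm]], paste(signif(vox, 4), collapse = "x"),
                   ref_path, paste(signif(ref_vox, 4), collapse = "x")))
    }
    channels[[nm]] <- arr
  }
  multi_contrast_volume(channels, voxel_size_mm = as.numeric(ref_vox),
                        subject_id = subject_id, timepoint = timepoint)
}

#' @rdname read_volume
#' @param path Path of a label NIfTI.
#' @export
read_mask <- function(path, subject_id = "subject", timepoint = 1L) {
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(as.array(img))
  seg_mask(array(as.integer(round(arr)), dim(arr)),
           voxel_size_mm = as.numeric(RNifti::pixdim(img)[1:3]),
           subject_id = subject_id, timepoint = timepoint)
}

#' Read / write a cohort manifest
#'
#' Delimited text (CSV) with one row per (subject, timepoint): file paths,
#' covariates, true volumes, landmark slice index, and the split label
#' (`train`/`val`/`test`/`none`). Split assignment is idempotent under a
#' write/read round trip.
#'
#' @param manifest A manifest `data.frame`.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(validate_manifest(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  validate_manifest(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_manifest <- function(manifest) {
  key <- paste(manifest$subject_id, manifest$timepoint)
  if (anyDuplicated(key)) stop("(subject_id, timepoint) pairs must be unique")
  if (!is.null(manifest$split)) {
    sp <- tapply(manifest$split, manifest$subject_id, function(x) length(unique(x)))
    if (any(sp > 1)) {
      stop("both timepoints of a subject must carry the same split assignment: ",
           paste(names(sp)[sp > 1], collapse = ", "))
    }
  }
  manifest
}

#' Select the analysis stack from a taller acquisition
#'
#' The anatomical landmark (the iliac crest in the emulated protocol) fixes
#' the inferior limit; the stack is that slice plus `n_superior` slices in
#' the superior direction (increasing slice index in RAS+), 51 slices in
#' total by default. Indices are 1-based, ranges inclusive-inclusive.
#'
#' @param n_total_slices Number of acquired slices.
#' @param landmark_index 1-based index of the landmark slice.
#' @param n_superior Number of additional superior slices (default 50).
#' @param slice_thickness_mm Slice thickness used to report the
#'   superior-inferior extent.
#' @return List with `i_start`, `i_end`, `n_slices`, `s_i_extent_mm`.
#' @export
select_analysis_stack <- function(n_total_slices, landmark_index,
                                  n_superior = 50L, slice_thickness_mm = 5) {
  stopifnot(landmark_index >= 1L, n_total_slices >= 1L)
  i_end <- landmark_index + n_superior
  if (i_end > n_total_slices) {
    stop(sprintf(paste0("not enough superior slices: need %d above the landmark ",
                        "but only %d are available"),
                 n_superior, n_total_slices - landmark_index))
  }
  list(i_start = as.integer(landmark_index), i_end = as.integer(i_end),
       n_slices = as.integer(n_superior + 1L),
       s_i_extent_mm = (n_superior + 1L) * slice_thickness_mm)
}

#' Load samples referenced by a cohort manifest
#'
#' Reads the per-channel NIfTI volumes and the mask for every manifest row
#' matching the requested time point (and split, when the manifest carries
#' one), in the form the trainer consumes.
#'
#' @param manifest A manifest `data.frame` with `path_op`, `path_water`,
#'   `path_fat`, `path_mask` columns.
#' @param timepoint Time point to load (1 or 2).
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @return List of samples `list(volume, mask)`.
#' @export
load_manifest_samples <- function(manifest, timepoint = 1L, split = NULL) {
  rows <- manifest[manifest$timepoint == timepoint, , drop = FALSE]
  if (!is.null(split)) rows <- rows[rows$split %in% split, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    vol <- read_volume(c(op = r$path_op, water = r$path_water, fat = r$path_fat),
                       subject_id = r$subject_id, timepoint = r$timepoint)
    mask <- read_mask(r$path_mask, subject_id = r$subject_id,
                      timepoint = r$timepoint)
    list(volume = vol, mask = mask)
  })
}
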