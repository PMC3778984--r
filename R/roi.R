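#' Mean value of a volume over an ROI mask
#'
#' @param volume 3D numeric array (e.g. FA in `[0, 1]`).
#' @param mask Logical (or 0/1) array of the same shape.
#' @return Arithmetic mean of the volume over mask voxels.
#' @examples
#' v <- array(0.5, c(4, 4, 4)); m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE
#' roi_mean(v, m)
#' @export
roi_mean <- function(volume, mask) {
  check_same_grid(volume, mask)
  mask <- as_binary_mask(mask)
  if (!any(mask)) abort("ROI mask is empty")
  mean(volume[mask])
}

check_same_grid <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da) || is.null(db) || length(da) != length(db) ||
      any(da != db)) {
    abort(paste0("grid mismatch: ", paste(da, collapse = "x"), " vs ",
                 paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) abort("mask must be binary (0/1 or logical)")
  array(mask != 0, dim = dim(mask))
}

#' Fractional-anisotropy asymmetry index
#'
#' `(FA_unaffected - FA_affected) / (FA_unaffected + FA_affected)`:
#' 0 for symmetric hemispheres, approaching 1 as the affected-hemisphere FA
#' vanishes, bounded in `[-1, 1]` for non-negative FA.
#'
#' @param fa_unaffected,fa_affected Mean FA of the contralesional /
#'   lesioned-hemisphere ROI (vectorized).
#' @return Unitless asymmetry index.
#' @examples
#' fa_asymmetry(0.54, 0.42)  # 0.125
#' @export
fa_asymmetry <- function(fa_unaffected, fa_affected) {
  s <- fa_unaffected + fa_affected
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("FA asymmetry undefined: FA values must be finite with a positive sum")
  }
  (fa_unaffected - fa_affected) / s
}

#' Volume of a binary mask in mm^3
#'
#' @param mask Binary array.
#' @param voxel_dims Voxel dimensions in mm (length 3).
#' @return Voxel count times voxel volume, mm^3.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[1:2, 1:4, 1:5] <- TRUE
#' mask_volume_mm3(m, c(2, 2, 2))  # 40 voxels x 8 mm^3
#' @export
mask_volume_mm3 <- function(mask, voxel_dims) {
  mask <- as_binary_mask(mask)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0)) {
    abort("`voxel_dims` must be three positive lengths (mm)")
  }
  sum(mask) * prod(voxel_dims)
}

#' Lesion overlap with a thresholded tract probability map
#'
#' Volume (mm^3) of voxels inside the lesion mask whose corticospinal-tract
#' probability meets the threshold. The threshold is expressed as a fraction
#' of the map's maximum (default 0.1), so maps scaled to any positive maximum
#' behave identically.
#'
#' @param lesion_mask Binary lesion array.
#' @param cst_prob_map Probability array on the same grid, values in `[0, 1]`.
#' @param voxel_dims Voxel dimensions in mm.
#' @param prob_threshold Threshold as a fraction of `max(cst_prob_map)`,
#'   in `[0, 1]`.
#' @return Overlap volume in mm^3 (never exceeds the lesion volume).
#' @export
lesion_cst_overlap <- function(lesion_mask, cst_prob_map, voxel_dims,
                               prob_threshold = 0.1) {
  check_same_grid(lesion_mask, cst_prob_map)
  lesion_mask <- as_binary_mask(lesion_mask)
  if (prob_threshold < 0 || prob_threshold > 1) {
    abort("`prob_threshold` must lie in [0, 1]")
  }
  if (any(cst_prob_map < 0 | cst_prob_map > 1)) {
    abort("CST probability map must have values in [0, 1]")
  }
  mx <- max(cst_prob_map)
  hit <- lesion_mask & (cst_prob_map >= prob_threshold * mx)
  mask_volume_mm3(hit, voxel_dims)
}

#' ROI FA statistics for one subject's volumes
#'
#' Computes per-hemisphere mean FA and the asymmetry index for the PLIC and
#' the ALIC control ROI, plus lesion volume and lesion--CST overlap.
#'
#' @param volumes An `fcr_volumes` object ([generate_fa_volume()]) or an
#'   equivalent list with `fa`, `masks`, `cst`, `voxel_dims`.
#' @param prob_threshold Forwarded to [lesion_cst_overlap()].
#' @return One-row tibble: `subject_id`, `fa_affected_plic`,
#'   `fa_unaffected_plic`, `fa_asymmetry_plic`, `fa_asymmetry_alic`,
#'   `lesion_volume`, `lesion_overlap` (mm^3).
#' @export
roi_stats <- function(volumes, prob_threshold = 0.1) {
  m <- volumes$masks
  fa_les <- roi_mean(volumes$fa, m$plic_lesioned)
  fa_con <- roi_mean(volumes$fa, m$plic_contralesional)
  alic_les <- roi_mean(volumes$fa, m$alic_lesioned)
  alic_con <- roi_mean(volumes$fa, m$alic_contralesional)
  tibble(
    subject_id = volumes$subject_id %||% NA_integer_,
    fa_affected_plic = fa_les,
    fa_unaffected_plic = fa_con,
    fa_asymmetry_plic = fa_asymmetry(fa_con, fa_les),
    fa_asymmetry_alic = fa_asymmetry(alic_con, alic_les),
    lesion_volume = mask_volume_mm3(m$lesion, volumes$voxel_dims),
    lesion_overlap = lesion_cst_overlap(m$lesion, volumes$cst,
                                        volumes$voxel_dims, prob_threshold)
  )
}

#' NIfTI-1 round-trip for volumes
#'
#' Thin wrappers over RNifti keeping the package's array-plus-voxel-dims
#' convention: `nifti_write()` stores a 3D array with voxel dimensions in the
#' header; `nifti_read()` returns `list(data, voxel_dims)`.
#'
#' @param volume 3D numeric array.
#' @param voxel_dims Voxel dimensions in mm.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `nifti_write()` the path invisibly; `nifti_read()` a list with
#'   `data` and `voxel_dims`.
#' @export
nifti_write <- function(volume, voxel_dims, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_write
#' @export
nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_dims = as.numeric(RNifti::pixdim(img))[seq_len(length(dim(img)))])
}

#' Write a subject's volume set as NIfTI files
#'
#' @param volumes An `fcr_volumes` object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_volumes <- function(volumes, dir, prefix = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  emit <- function(arr, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    nifti_write(arr * 1, volumes$voxel_dims, p)
    p
  }
  paths["fa"] <- emit(volumes$fa, "fa")
  for (nm in names(volumes$masks)) {
    paths[nm] <- emit(volumes$masks[[nm]], nm)
  }
  paths["cst"] <- emit(volumes$cst, "cst")
  invisible(paths)
}
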