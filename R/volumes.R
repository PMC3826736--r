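#' Build a tissue mask by thresholding a probability template
#'
#' Flags voxels whose template value strictly exceeds the threshold (0.5 by
#' default), the rule used to cut subject-level tissue maps down to the
#' voxels that plausibly belong to the tissue class. Strict inequality is
#' the documented convention: a template exactly at the threshold is
#' excluded.
#'
#' @param template a 3D array or an `RNifti` image of tissue probabilities.
#' @param threshold exclusive lower bound for inclusion.
#' @return an object of class `"tissue_mask"` with `shape`, `flags`
#'   (logical array), `voxel_count`, `affine` (4x4 voxel-to-world transform,
#'   identity when the template carries none) and `voxel_size_mm`.
#' @export
build_mask <- function(template, threshold = 0.5) {
  arr <- as.array(template)
  if (length(dim(arr)) != 3) stop("template must be a 3D volume")
  affine <- diag(4)
  voxdim <- c(1, 1, 1)
  if (inherits(template, "niftiImage") ||
      !is.null(attr(template, "pixdim"))) {
    voxdim <- RNifti::pixdim(template)[1:3]
    affine <- tryCatch(unclass(RNifti::xform(template)),
                       error = function(e) diag(4))
  }
  flags <- arr > threshold
  structure(list(shape = dim(arr), flags = flags,
                 voxel_count = sum(flags), affine = affine,
                 voxel_size_mm = voxdim),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask %s: %d of %d voxels flagged\n",
              paste(x$shape, collapse = "x"), x$voxel_count,
              prod(x$shape)))
  invisible(x)
}

#' Do two masks overlap?
#'
#' Tissue masks of different classes are expected to be disjoint; this
#' checks the pairwise intersection.
#'
#' @param a,b `"tissue_mask"` objects of the same shape.
#' @return number of voxels flagged in both.
#' @export
mask_overlap <- function(a, b) {
  stopifnot(inherits(a, "tissue_mask"), inherits(b, "tissue_mask"),
            identical(a$shape, b$shape))
  sum(a$flags & b$flags)
}

#' Vectorize per-subject volumes through a mask
#'
#' Reduces each subject's 3D volume to its masked voxels, in the fixed scan
#' order (fastest-varying first axis, R's native array linearization), and
#' stacks them into a subjects x voxels feature matrix. Column names are the
#' voxel linear indices within the full grid, so maps can be written back.
#' Exact inverse of [map_to_volume()] on the masked voxels.
#'
#' @param volumes list of 3D arrays (one per subject), or a 4D array with
#'   subjects on the 4th dimension.
#' @param mask a `"tissue_mask"` of matching shape.
#' @return numeric matrix, one row per subject.
#' @export
vectorize_volumes <- function(volumes, mask) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (mask$voxel_count == 0)
    stop("mask is empty: refusing to build a 0-column feature matrix")
  if (is.array(volumes) && length(dim(volumes)) == 4)
    volumes <- lapply(seq_len(dim(volumes)[4]),
                      function(i) volumes[, , , i])
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  idx <- which(mask$flags)
  rows <- lapply(seq_along(volumes), function(i) {
    v <- as.array(volumes[[i]])
    if (!identical(dim(v), as.integer(mask$shape)) &&
        !identical(as.integer(dim(v)), as.integer(mask$shape)))
      stop(sprintf("subject %d volume shape (%s) does not match mask (%s)",
                   i, paste(dim(v), collapse = "x"),
                   paste(mask$shape, collapse = "x")))
    as.numeric(v)[idx]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- as.character(idx)
  if (!is.null(names(volumes))) rownames(m) <- names(volumes)
  m
}

#' Write per-voxel values back into masked volume space
#'
#' Unmasked voxels are zero; masked voxels receive the values in mask scan
#' order. `vectorize_volumes(map_to_volume(v, mask), mask)` returns `v`
#' exactly.
#'
#' @param values numeric vector of length `mask$voxel_count`, or a
#'   `"discriminative_map"` (its ratios are used).
#' @param mask the `"tissue_mask"`.
#' @return 3D array of the mask's shape.
#' @export
map_to_volume <- function(values, mask) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (inherits(values, "discriminative_map")) values <- values$ratio
  if (length(values) != mask$voxel_count)
    stop(sprintf("map length %d does not match mask voxel count %d",
                 length(values), mask$voxel_count))
  vol <- array(0, dim = mask$shape)
  vol[which(mask$flags)] <- values
  vol
}

#' Write a volume (or discriminative map) as NIfTI-1
#'
#' The mask's affine and voxel size are attached; orientation is recorded in
#' the header rather than resampled.
#'
#' @param volume 3D array.
#' @param mask `"tissue_mask"` supplying geometry.
#' @param path output file (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, mask, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path a `.nii` / `.nii.gz` file.
#' @export
read_volume <- function(path) RNifti::readNifti(path)
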