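#' Brain mask on a voxel grid
#'
#' A logical array over a [vox_geometry()] grid marking the voxels that take
#' part in the analysis (the "brain-interior" voxels). Matrix columns of a
#' [subject_matrix()] enumerate the `TRUE` entries in fixed x-fastest scan
#' order, so the mask fully determines the feature indexing.
#'
#' @param inside Logical array with `dim(inside) == geometry$shape`.
#' @param geometry A [vox_geometry()].
#' @return An object of class `brain_mask` with fields `geometry`, `inside`
#'   and `n_inside`.
#' @export
brain_mask <- function(inside, geometry) {
  if (!is.logical(inside)) stop("'inside' must be a logical array")
  if (!identical(dim(inside), as.integer(geometry$shape)))
    stop("mask dimensions do not match the geometry")
  n <- sum(inside)
  if (n < 1L) stop("mask has no interior voxels")
  structure(list(geometry = geometry, inside = inside, n_inside = n),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d interior voxels of %d (%.1f%%)\n",
              x$n_inside, prod(x$geometry$shape),
              100 * x$n_inside / prod(x$geometry$shape)))
  invisible(x)
}

#' Construct a deterministic analysis mask
#'
#' `full_box` marks every voxel interior. `ellipsoid` inscribes an ellipsoid
#' in the box with semi-axes `shape/2 - 1` voxels, a crude but
#' brain-volume-scale stand-in for a skull-stripped mask.
#'
#' @param shape Integer triple of grid dimensions; each entry must be >= 4
#'   for the ellipsoid.
#' @param kind `"ellipsoid"` or `"full_box"`.
#' @param geometry Optional [vox_geometry()]; defaults to
#'   `vox_geometry(shape)` with 2 mm voxels.
#' @return A [brain_mask()].
#' @examples
#' make_mask(c(4, 4, 4), "full_box")$n_inside  # 64
#' @export
make_mask <- function(shape, kind = c("ellipsoid", "full_box"),
                      geometry = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (is.null(geometry)) geometry <- vox_geometry(shape)
  if (!all(shape == geometry$shape)) stop("'shape' conflicts with 'geometry'")
  if (kind == "full_box") {
    inside <- array(TRUE, shape)
  } else {
    if (any(shape < 4L)) stop("ellipsoid mask needs all shape entries >= 4")
    semi <- shape / 2 - 1
    ctr <- (shape + 1) / 2              # 1-based grid centre
    gx <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
    gy <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
    gz <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
    inside <- outer(outer(gx, gy, "+"), gz, "+") <= 1
  }
  brain_mask(inside, geometry)
}

#' Read a mask volume from a NIfTI file
#'
#' Any voxel with a nonzero, non-missing value is treated as interior.
#'
#' @param path Path to a NIfTI file.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("mask must be a single 3D volume: ", path)
  inside <- !is.na(arr) & arr != 0
  brain_mask(inside, geometry_from_nifti(img))
}

#' Write a mask to a NIfTI file
#'
#' @param mask A [brain_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_volume(array(as.integer(mask$inside), mask$geometry$shape),
                     mask$geometry, path)
}

## 0-based coordinates of the mask-interior voxels in x-fastest scan order.
mask_coords <- function(mask) {
  idx <- which(mask$inside)
  arrayInd(idx, mask$geometry$shape) - 1L
}
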