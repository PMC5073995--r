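#' Voxel grid geometry
#'
#' Describes the lattice a set of co-registered volumes lives on: grid
#' dimensions, physical voxel size and the 4x4 affine mapping 0-based voxel
#' indices to world (scanner/MNI) millimetre coordinates.
#'
#' @param shape Integer triple `(nx, ny, nz)`, all entries >= 1.
#' @param voxel_size_mm Real triple of voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world transform. Defaults to a
#'   diagonal scaling by `voxel_size_mm` with the grid centre at the world
#'   origin.
#' @return An object of class `vox_geometry` with fields `shape`,
#'   `voxel_size_mm` and `affine`.
#' @examples
#' g <- vox_geometry(c(79, 95, 69), c(2, 2, 2))
#' g$shape
#' @export
vox_geometry <- function(shape, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be an integer triple with all entries >= 1")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive real triple")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- -(shape - 1) / 2 * voxel_size_mm
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "vox_geometry")
}

#' @export
print.vox_geometry <- function(x, ...) {
  cat(sprintf("<vox_geometry> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

## Geometry of an on-disk or in-memory NIfTI image.
geometry_from_nifti <- function(img) {
  d <- dim(img)[1:3]
  vox_geometry(d, RNifti::pixdim(img)[1:3], unclass(RNifti::xform(img)))
}

geometry_equal <- function(a, b, tol = 1e-4) {
  all(a$shape == b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

#' Convert 0-based voxel coordinates to world millimetres
#'
#' @param coords Integer matrix (n x 3) of 0-based voxel indices, or a
#'   length-3 vector.
#' @param geometry A [vox_geometry()].
#' @return Numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_mm <- function(coords, geometry) {
  coords <- rbind_coords(coords)
  h <- cbind(coords, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

## Accept a single triple or an n x 3 matrix; always return a matrix.
rbind_coords <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coordinates must have three columns")
  coords
}

## Injective scalar key for integer lattice coordinates, x fastest.  Shape
## is padded by 2 so that +/-1 neighbour offsets never collide across rows.
vox_key <- function(coords, shape) {
  coords[, 1] + (shape[1] + 2) * (coords[, 2] + (shape[2] + 2) * coords[, 3])
}

## Write a 3D array as NIfTI carrying the geometry's affine.
write_nifti_volume <- function(arr, geometry, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$voxel_size_mm
  RNifti::qform(img) <- structure(geometry$affine, code = 2L)
  RNifti::sform(img) <- structure(geometry$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
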