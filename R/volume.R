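#' Volumetric image with a voxel-to-world affine
#'
#' A `volume_image` is the package's container for 3-D brain maps: a numeric
#' array of voxel values plus a 4x4 affine mapping 0-based voxel indices to
#' MNI millimetre coordinates. Missing (out-of-mask) voxels are `NA`.
#'
#' @param values numeric 3-D array.
#' @param affine 4x4 numeric matrix, invertible; last row `(0,0,0,1)`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, affine) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("`affine` is singular")
  structure(list(values = values, affine = unname(affine)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  vs <- voxel_sizes(x$affine)
  cat(sprintf("<volume_image> %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: range [%.4g, %.4g], %d missing\n",
                min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' Per-axis voxel sizes (mm) implied by an affine
#' @param affine 4x4 affine matrix.
#' @return length-3 numeric vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Construct an empty MNI-like template grid
#'
#' Default grid is the standard 2 mm isotropic MNI space (91 x 109 x 91,
#' RAS-oriented affine with the origin at the anterior commissure). Smaller
#' grids keep the same voxel size and re-centre the origin so that coordinate
#' (0,0,0) mm falls on a voxel center.
#'
#' @param dim integer length-3 voxel counts.
#' @param voxel_mm voxel edge length in mm (isotropic).
#' @param fill initial voxel value.
#' @return A `volume_image` filled with `fill`.
#' @export
mni_grid <- function(dim = c(91L, 109L, 91L), voxel_mm = 2, fill = 0) {
  dim <- as.integer(dim)
  if (all(dim == c(91L, 109L, 91L)) && voxel_mm == 2) {
    affine <- rbind(c(-2, 0, 0, 90),
                    c(0, 2, 0, -126),
                    c(0, 0, 2, -72),
                    c(0, 0, 0, 1))
  } else {
    # centre the grid on the origin, voxel centers on a voxel_mm lattice
    orig <- -voxel_mm * floor(dim / 2)
    affine <- rbind(c(voxel_mm, 0, 0, orig[1]),
                    c(0, voxel_mm, 0, orig[2]),
                    c(0, 0, voxel_mm, orig[3]),
                    c(0, 0, 0, 1))
  }
  volume_image(array(fill, dim = dim), affine)
}

#' Convert 0-based voxel indices to world (MNI mm) coordinates
#' @param vox numeric matrix (n x 3) of 0-based voxel indices (may be fractional).
#' @param affine 4x4 affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
vox_to_mm <- function(vox, affine) {
  vox <- matrix(as.numeric(vox), ncol = 3L)
  t(affine[1:3, 1:3] %*% t(vox) + affine[1:3, 4])
}

#' Convert world (MNI mm) coordinates to 0-based voxel indices
#' @param mm numeric matrix (n x 3) of mm coordinates.
#' @param affine 4x4 affine.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
mm_to_vox <- function(mm, affine) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(mm) + inv[1:3, 4])
}

# mm coordinates of every voxel center, in array (column-major) order
voxel_center_mm <- function(img) {
  d <- dim(img$values)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  vox_to_mm(idx, img$affine)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Read a NIfTI-1 volume as a `volume_image`
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `volume_image`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  arr <- array(as.numeric(arr), dim(arr))   # strip NIfTI attributes
  volume_image(arr, aff)
}

#' Write a `volume_image` to NIfTI-1
#' @param img a `volume_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(is_volume_image(img))
  nim <- RNifti::asNifti(img$values)
  RNifti::pixdim(nim) <- voxel_sizes(img$affine)
  RNifti::qform(nim) <- structure(img$affine, code = 2L)
  RNifti::sform(nim) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}
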