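#' Tract volume: a 3-D scalar field with a voxel-to-world affine
#'
#' Container for a tract probability map, metric map or binary mask together
#' with the 4x4 affine that maps 0-based voxel indices to world millimetres
#' (the NIfTI convention).
#'
#' @param data 3-D numeric or logical array, non-negative.
#' @param affine 4x4 invertible voxel-index-to-mm matrix. Default: identity
#'   scaled by `voxel_mm`.
#' @param voxel_mm Isotropic voxel size used when `affine` is missing.
#' @param threshold Probability cutoff that was (or will be) applied to
#'   define the foreground; default `5e-5`, the standard false-positive
#'   threshold for probabilistic tractography output.
#' @return An object of class `tract_volume`.
#' @export
tract_volume <- function(data, affine = NULL, voxel_mm = 2, threshold = 5e-5) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  if (any(data < 0, na.rm = TRUE)) stop("volume data must be non-negative")
  structure(list(data = data, affine = affine, threshold = threshold),
            class = "tract_volume")
}

#' @export
print.tract_volume <- function(x, ...) {
  cat(sprintf("tract_volume: %s grid, %d foreground voxels (threshold %g)\n",
              paste(dim(x$data), collapse = "x"),
              sum(x$data >= x$threshold & x$data > 0), x$threshold))
  invisible(x)
}

## foreground mask at the volume's threshold
vol_foreground <- function(vol) {
  vol$data >= vol$threshold & vol$data > 0
}

## 1-based voxel index matrix (n x 3) -> world mm (n x 3), NIfTI 0-based affine
voxels_to_world <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  xyz <- cbind(idx - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

## world mm (n x 3) -> continuous 1-based voxel index (n x 3)
world_to_voxels <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  idx0 <- cbind(xyz, 1) %*% t(solve(affine))
  idx0[, 1:3, drop = FALSE] + 1
}

## mm voxel edge lengths from an affine
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

## logical array -> n x 3 matrix of 1-based indices
mask_to_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}

## connected-component labels of a logical array (26 or 6 connectivity)
label_components <- function(mask, connectivity = 26) {
  lab <- label_components_cpp(as.logical(mask), dim(mask), connectivity)
  array(lab, dim(mask))
}
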