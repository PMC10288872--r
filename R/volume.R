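#' 3D volume with a voxel-to-world affine
#'
#' A `cc_volume` couples a 3D scalar array with a 4x4 affine mapping 0-based
#' voxel indices (i, j, k) to world coordinates in RAS millimetres. Voxel
#' (i, j, k) occupies the half-open box centred on `affine %*% c(i, j, k, 1)`.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, last row `c(0, 0, 0, 1)`, invertible.
#' @return An object of class `cc_volume`.
#' @export
cc_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine is singular")
  structure(list(data = data, affine = affine), class = "cc_volume")
}

#' @export
print.cc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cc_volume> %d x %d x %d, voxel %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_sizes(x$affine), 4), collapse = " x ")))
  invisible(x)
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

## world mm -> continuous 0-based voxel index (n x 3 in, n x 3 out)
world_to_voxel <- function(affine, pts) {
  pts <- matrix(pts, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

## 0-based voxel indices -> world mm of voxel centres
voxel_to_world <- function(affine, idx) {
  idx <- matrix(idx, ncol = 3)
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

#' Validate a volume as a binary mask
#'
#' @param vol A [cc_volume()].
#' @return The volume, invisibly, after checking all values are finite and in
#'   \{0, 1\}.
#' @export
validate_mask <- function(vol) {
  v <- vol$data
  if (any(!is.finite(v)))
    stop("mask contains non-finite values")
  if (!all(v %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  invisible(vol)
}

#' Validate a volume as a 7-label parcellation
#'
#' Label volumes code background as 0 and the seven anterior-posterior
#' cortical parcels as 1-7.
#'
#' @param vol A [cc_volume()].
#' @param max_label Largest admissible label (default 7).
#' @return The volume, invisibly.
#' @export
validate_labels <- function(vol, max_label = 7L) {
  v <- vol$data
  if (any(!is.finite(v)))
    stop("label volume contains non-finite values")
  if (any(v != round(v)))
    stop("label volume contains non-integer values")
  if (any(v < 0) || any(v > max_label))
    stop(sprintf("label codes must lie in 0..%d", max_label))
  invisible(vol)
}
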