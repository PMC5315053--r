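#' Define a regular voxel grid
#'
#' A `VolumeGrid` describes an axis-aligned 3D sampling lattice: the number
#' of voxels along each axis, the voxel pitch in mm, and the mm coordinate of
#' the centre of voxel (1,1,1).  The voxel-to-mm mapping is the affine
#' `mm = origin + (index - 1) * voxel_size`, applied per axis.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric length 1 or 3, voxel pitch in mm (all > 0).
#'   Default 2 mm isotropic, the grid spacing used throughout the analyses.
#' @param origin numeric length 3, mm coordinate of the centre of the first
#'   voxel.  Defaults to centring the grid on the mm origin.
#' @return An object of class `VolumeGrid`.
#' @export
volume_grid <- function(shape, voxel_size = 2, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "VolumeGrid")
}

#' @export
print.VolumeGrid <- function(x, ...) {
  cat(sprintf("VolumeGrid: %s voxels, %s mm pitch, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' 4x4 voxel-to-mm affine of a grid
#'
#' Uses 0-based voxel indices, i.e. `mm = A %*% c(i0, j0, k0, 1)` where
#' `i0 = i - 1` for the 1-based R index `i` (the NIfTI convention).
#'
#' @param grid a [volume_grid()].
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  diag(A)[1:3] <- grid$voxel_size
  A[1:3, 4] <- grid$origin
  A
}

#' Convert between voxel indices and mm coordinates
#'
#' `vox_to_mm()` maps 1-based voxel indices to mm; `mm_to_vox()` is the
#' inverse (returning fractional indices; round to land on a voxel).
#'
#' @param grid a [volume_grid()].
#' @param vox,mm numeric vector of length 3 or matrix with 3 columns.
#' @return Same shape as the input, converted.
#' @export
vox_to_mm <- function(grid, vox) {
  v <- rbind(vox)
  sweep(sweep(v - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")[seq_len(NROW(rbind(vox))), , drop = !is.matrix(vox)]
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(grid, mm) {
  m <- rbind(mm)
  out <- sweep(sweep(m, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
  out[seq_len(NROW(m)), , drop = !is.matrix(mm)]
}

#' Reconstruct a grid from a NIfTI-style affine
#'
#' Only axis-aligned affines (diagonal rotation part with positive scales)
#' are supported; anything else is rejected.
#'
#' @param affine 4x4 matrix.
#' @param shape integer triple.
#' @return A [volume_grid()].
#' @export
grid_from_affine <- function(affine, shape) {
  R <- affine[1:3, 1:3]
  offdiag <- R - diag(diag(R))
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(R))))
    stop("affine is not axis-aligned; oblique grids are not supported")
  if (any(diag(R) <= 0))
    stop("affine has non-positive voxel scales")
  volume_grid(shape, voxel_size = diag(R), origin = affine[1:3, 4])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}
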