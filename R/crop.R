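#' Bounding box of a mask
#'
#' Index ranges of the smallest axis-aligned box containing all TRUE
#' voxels, optionally padded.
#'
#' @param mask 3D logical array.
#' @param margin_voxels padding per side (clipped at the volume edge).
#' @return List of three integer ranges (`x`, `y`, `z`).
#' @export
bounding_box <- function(mask, margin_voxels = 0) {
  stopifnot(length(dim(mask)) == 3L)
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("mask is empty")
  co <- arrayInd(idx, dim(mask))
  s <- dim(mask)
  rng <- lapply(1:3, function(a)
    seq(max(1L, min(co[, a]) - margin_voxels),
        min(s[a], max(co[, a]) + margin_voxels)))
  names(rng) <- c("x", "y", "z")
  rng
}

#' Crop a volume or mask to a bounding box
#'
#' @param volume 3D or 4D array (trailing dimensions kept whole).
#' @param box a [bounding_box()].
#' @return The cropped array.
#' @export
crop_volume <- function(volume, box) {
  nd <- length(dim(volume))
  args <- c(list(volume), box, rep(list(quote(expr = )), nd - 3L),
            list(drop = FALSE))
  out <- do.call(`[`, args)
  if (nd == 3L) dim(out) <- vapply(box, length, integer(1))
  out
}

#' Crop a BOLD run to a bounding box
#'
#' The grid origin is shifted so mm coordinates of retained voxels are
#' unchanged.
#'
#' @param run a [bold_run()].
#' @param box a [bounding_box()].
#' @return A cropped [bold_run()].
#' @export
crop_run <- function(run, box) {
  g <- run$grid
  new_grid <- volume_grid(vapply(box, length, integer(1)), g$voxel_size,
                          origin = vox_to_mm(g, vapply(box, min, numeric(1))))
  bold_run(crop_volume(run$data, box), new_grid, run$tr, run$motion_params)
}
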