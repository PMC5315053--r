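#' Construct a BOLD run
#'
#' A `BoldRun` bundles one 4D acquisition: the sampling grid, repetition
#' time, the data array (x, y, z, time) and six rigid-body motion
#' parameters per timepoint (3 translations in mm, 3 rotations in rad).
#'
#' @param data 4D numeric array.
#' @param grid a [volume_grid()] matching `dim(data)[1:3]`.
#' @param tr repetition time, s.
#' @param motion_params optional time x 6 matrix; defaults to zeros.
#' @return A `BoldRun` object.
#' @export
bold_run <- function(data, grid, tr, motion_params = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("data spatial dimensions do not match the grid")
  n_t <- dim(data)[4]
  if (n_t < 2L) stop("a BoldRun needs at least 2 timepoints")
  if (any(!is.finite(data))) stop("BOLD data must be finite")
  check_scalar(tr, "tr", lower = .Machine$double.eps)
  if (is.null(motion_params))
    motion_params <- matrix(0, nrow = n_t, ncol = 6,
                            dimnames = list(NULL, c("tx", "ty", "tz",
                                                    "rx", "ry", "rz")))
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) != n_t || ncol(motion_params) != 6L)
    stop("motion_params must be a (timepoints x 6) matrix")
  structure(list(data = data, grid = grid, tr = tr,
                 motion_params = motion_params),
            class = "BoldRun")
}

#' @export
print.BoldRun <- function(x, ...) {
  cat(sprintf("BoldRun: %s voxels x %d volumes, TR = %g s\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4], x$tr))
  invisible(x)
}

# time x voxel matrix view of a run's data
run_matrix <- function(run) {
  d <- run$data
  dim(d) <- c(prod(dim(d)[1:3]), dim(d)[4])
  t(d)
}
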