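#' Write a volume (3D or 4D) as NIfTI-1
#'
#' The grid's affine is stored in the sform/qform; data are written as
#' float64 so round trips are exact to numerical precision.
#'
#' @param volume 3D/4D numeric array, or a [bold_run()] (its data are
#'   written and its grid used).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a [volume_grid()]; taken from `volume` when it is a BoldRun.
#' @param datatype NIfTI storage type (default `"double"`; use `"int32"`
#'   for label atlases).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, grid = NULL, datatype = "double") {
  tr <- NULL
  if (inherits(volume, "BoldRun")) {
    grid <- volume$grid
    tr <- volume$tr
    volume <- volume$data
  }
  if (is.null(grid)) stop("a grid is required to write a bare array")
  nd <- length(dim(volume))
  if (!nd %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  if (!identical(as.integer(dim(volume)[1:3]), grid$shape))
    stop("volume spatial dimensions do not match the grid")
  img <- RNifti::asNifti(volume)
  aff <- grid_affine(grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  if (!is.null(tr))
    RNifti::pixdim(img) <- c(grid$voxel_size, tr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @return List with `data` (3D array) and `grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s' is %dD; expected a 3D volume", path, length(d)))
  grid <- grid_from_affine(structure(RNifti::xform(img), dim = c(4, 4)), d)
  list(data = array(as.numeric(img), dim = d), grid = grid)
}

#' Read a 4D BOLD run from NIfTI-1
#'
#' The repetition time is taken from the file's pixdim unless overridden.
#'
#' @param path NIfTI file.
#' @param tr repetition time override, s.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is %dD; expected a 4D BOLD series", path, length(d)))
  grid <- grid_from_affine(structure(RNifti::xform(img), dim = c(4, 4)), d[1:3])
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop(sprintf("'%s' has no usable TR in pixdim; pass tr= explicitly", path))
  }
  bold_run(array(as.numeric(img), dim = d), grid, tr)
}

#' Write an event table as tab-separated text (BIDS events dialect)
#'
#' @param events an `EventTable`.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("onset", "duration",
                                               "trial_type", "run")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an event table
#'
#' Expects a tab-separated file with header columns onset, duration,
#' trial_type and run.  Rows are canonicalised (sorted by run, then onset);
#' overlapping blocks, negative onsets and unknown condition labels are
#' rejected with the offending row identified.
#'
#' @param path `.tsv` file.
#' @param conditions allowed condition labels (default [task_conditions()];
#'   NULL skips the check).
#' @return An `EventTable`.
#' @export
read_events <- function(path, conditions = task_conditions()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_event_table(df, conditions, file = path)
  new_event_table(df[, c("onset", "duration", "trial_type", "run")],
                  conditions %||% unique(df$trial_type))
}
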