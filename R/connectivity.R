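#' Spherical seed ROI mask
#'
#' Voxels whose centres lie within `radius` mm of the seed centre.
#'
#' @param center mm coordinates, length 3.
#' @param radius sphere radius, mm (> 0).  The connectivity seeds follow
#'   the 6 mm *diameter* convention (radius 3), while the univariate
#'   percent-signal-change ROIs use 6 mm radius spheres; both are explicit
#'   here.
#' @param grid a [volume_grid()].
#' @param name optional seed label carried in the attribute.
#' @return 3D logical mask with attributes `name`, `center`, `radius`.
#' @export
sphere_roi_mask <- function(center, radius, grid, name = NULL) {
  stopifnot(radius > 0, length(center) == 3)
  cv <- mm_to_vox(grid, as.numeric(center))
  if (any(cv < 0.5) || any(cv > grid$shape + 0.5))
    stop("seed centre lies outside the grid")
  d2 <- .dist2_to(grid, cv)
  mask <- d2 <= radius^2 + 1e-9
  if (!any(mask))
    stop("empty seed mask: radius ", radius,
         " mm captures no voxel centre on this grid; increase the radius")
  attr(mask, "name") <- name
  attr(mask, "center") <- center
  attr(mask, "radius") <- radius
  mask
}

#' CompCor nuisance components
#'
#' Principal-component time courses of the WM and CSF compartments: voxel
#' time series from the union mask are demeaned and variance-normalised,
#' and the top `k` left singular vectors (orthonormal component time
#' courses) are returned.  If the data rank is below `k`, the available
#' components are returned with a recorded warning.
#'
#' @param run a [bold_run()].
#' @param wm_mask,csf_mask 3D logical compartment masks (union must be
#'   non-empty).
#' @param k number of components (default 5).
#' @return Timepoints x k matrix with columns `compcor_1..k`; attribute
#'   `warning` when rank-limited.
#' @export
compcor <- function(run, wm_mask, csf_mask, k = 5) {
  stopifnot(k >= 1)
  sel <- which(as.logical(wm_mask) | as.logical(csf_mask))
  if (!length(sel)) stop("WM/CSF masks are empty")
  Y <- run_matrix(run)[, sel, drop = FALSE]
  Y <- sweep(Y, 2, colMeans(Y))
  sds <- col_sds(Y)
  Y <- Y[, sds > 0, drop = FALSE]
  Y <- sweep(Y, 2, sds[sds > 0], "/")
  if (!ncol(Y)) stop("all WM/CSF voxels have zero variance")
  sv <- svd(Y, nu = min(k, min(dim(Y))), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  k_eff <- min(k, rank)
  comp <- sv$u[, seq_len(k_eff), drop = FALSE]
  colnames(comp) <- paste0("compcor_", seq_len(k_eff))
  if (k_eff < k)
    attr(comp, "warning") <- sprintf(
      "requested %d components but data rank is %d", k, rank)
  comp
}

# T x T Gaussian temporal smoothing operator (row-normalised)
.temporal_smoother <- function(n_t, tr, sigma_s) {
  t_s <- (seq_len(n_t) - 1) * tr
  W <- exp(-outer(t_s, t_s, "-")^2 / (2 * sigma_s^2))
  W / rowSums(W)
}

#' Regress nuisance confounds out of a run, with temporal band filtering
#'
#' Per voxel, the data are replaced by the residual of an OLS fit on the
#' confound columns plus an intercept.  Exactly collinear confounds are
#' dropped with a recorded warning.  Optionally, Gaussian temporal band
#' filtering is then applied: high-pass as the residual from a
#' Gaussian-weighted running mean with `band[1]` seconds sigma, low-pass as
#' Gaussian smoothing with `band[2]` seconds sigma (either may be NA to
#' skip; `band = NULL` skips filtering entirely, keeping the regression
#' step idempotent).
#'
#' @param run a [bold_run()].
#' @param confounds numeric matrix (timepoints x q), e.g.
#'   `cbind(compcor(...), run$motion_params)`.
#' @param band length-2 numeric `(highpass_sigma_s, lowpass_sigma_s)`,
#'   default `c(100, 2.8)`, or NULL.
#' @return A cleaned [bold_run()]; attribute `dropped_confounds` lists any
#'   removed columns.
#' @export
regress_confounds <- function(run, confounds, band = c(100, 2.8)) {
  X <- as.matrix(confounds)
  n_t <- dim(run$data)[4]
  if (nrow(X) != n_t) stop("confound rows must equal run timepoints")
  if (any(!is.finite(X))) stop("confounds contain non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("confound_", seq_len(ncol(X)))
  Xi <- cbind(intercept = 1, X)
  qrX <- qr(Xi)
  dropped <- character(0)
  if (qrX$rank < ncol(Xi)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(Xi)[-keep]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    Xi <- Xi[, sort(keep), drop = FALSE]
    qrX <- qr(Xi)
  }
  Y <- run_matrix(run)
  R <- Y - Xi %*% qr.coef(qrX, Y)
  if (!is.null(band)) {
    if (!is.na(band[1])) R <- R - .temporal_smoother(n_t, run$tr, band[1]) %*% R
    if (!is.na(band[2])) R <- .temporal_smoother(n_t, run$tr, band[2]) %*% R
  }
  out <- bold_run(array(t(R), dim = dim(run$data)), run$grid, run$tr,
                  run$motion_params)
  attr(out, "dropped_confounds") <- dropped
  out
}

#' Seed-based connectivity map
#'
#' The seed time course is the mean over seed voxels; every voxel's Pearson
#' correlation with it is Fisher z-transformed (`atanh`).  Voxels with
#' |r| above 0.999999 (the seed interior correlating with itself) are
#' capped at `atanh(0.999999)` and flagged; zero-variance voxels are
#' invalid.
#'
#' @param run a cleaned [bold_run()].
#' @param seed_mask 3D logical seed mask (non-empty).
#' @param name seed label.
#' @return A `ConnectivityMap`: list with `values` (3D Fisher z), `valid`,
#'   `flagged`, `grid`, `seed_name`, `n_timepoints`.
#' @export
seed_map <- function(run, seed_mask, name = attr(seed_mask, "name") %||% "seed") {
  sel <- which(as.logical(seed_mask))
  if (!length(sel)) stop("seed mask is empty")
  Y <- run_matrix(run)
  ts <- rowMeans(Y[, sel, drop = FALSE])
  if (stats::sd(ts) == 0) stop("seed time course has zero variance")
  sds <- col_sds(Y)
  ok <- sds > 0
  r <- rep(NA_real_, ncol(Y))
  tsc <- ts - mean(ts)
  num <- crossprod(tsc, sweep(Y[, ok, drop = FALSE], 2,
                              colMeans(Y[, ok, drop = FALSE])))
  r[ok] <- as.numeric(num) / ((nrow(Y) - 1) * stats::sd(ts) * sds[ok])
  cap <- 0.999999
  flag <- !is.na(r) & abs(r) > cap
  r[flag] <- sign(r[flag]) * cap
  z <- atanh(r)
  s <- run$grid$shape
  structure(list(values = array(z, dim = s),
                 valid = array(ok, dim = s),
                 flagged = array(flag, dim = s),
                 grid = run$grid, seed_name = name,
                 n_timepoints = nrow(Y)),
            class = "ConnectivityMap")
}

#' Paired seed contrast with group inference
#'
#' Per-subject difference of two seed connectivity maps (A - B), tested
#' against zero with the shared sign-flip cluster-mass machinery of
#' [group_chance_test()].
#'
#' @param mapsA,mapsB same-length lists of per-subject `ConnectivityMap`s,
#'   pairwise on the same grid.
#' @param ... passed to [group_chance_test()] (`cluster_forming_z`,
#'   `n_perm`, `seed`, `alpha`).
#' @return A `GroupResult`.
#' @export
seed_contrast <- function(mapsA, mapsB, ...) {
  if (length(mapsA) != length(mapsB))
    stop("mapsA and mapsB must pair the same subjects")
  diffs <- lapply(seq_along(mapsA), function(i) {
    a <- mapsA[[i]]; b <- mapsB[[i]]
    if (!same_grid(a$grid, b$grid)) stop("paired maps are on different grids")
    list(values = a$values - b$values, valid = a$valid & b$valid,
         grid = a$grid)
  })
  group_chance_test(diffs, chance = 0, ...)
}

#' Overlap of a thresholded map with template networks
#'
#' For each template: the number of overlapping voxels and the proportion
#' of the input map's voxels falling inside the template.
#'
#' @param binary_map 3D logical (thresholded) map.
#' @param templates named list of 3D logical template networks on the same
#'   grid.
#' @return Data frame with columns network, overlap_voxels, proportion
#'   (NA with attribute `empty_map = TRUE` when the input map is empty).
#' @export
network_overlap <- function(binary_map, templates) {
  stopifnot(length(templates) >= 1, !is.null(names(templates)))
  m <- as.logical(binary_map)
  n_map <- sum(m)
  out <- data.frame(
    network = names(templates),
    overlap_voxels = vapply(templates, function(tp) {
      if (!identical(dim(binary_map), dim(tp)))
        stop("template grid does not match the map")
      sum(m & as.logical(tp))
    }, integer(1)),
    row.names = NULL)
  out$proportion <- if (n_map == 0) NA_real_ else out$overlap_voxels / n_map
  attr(out, "empty_map") <- n_map == 0
  attr(out, "map_voxels") <- n_map
  out
}
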