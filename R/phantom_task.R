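# smooth random-walk motion traces (used only as confound regressors)
simulate_motion <- function(n_t, trans_sd = 0.02, rot_sd = 2e-4) {
  steps <- cbind(matrix(stats::rnorm(n_t * 3, sd = trans_sd), n_t),
                 matrix(stats::rnorm(n_t * 3, sd = rot_sd), n_t))
  mp <- apply(steps, 2, cumsum)
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mp
}

# AR(1)-filtered Gaussian noise, stationary initialisation, time x voxel
ar1_noise <- function(n_t, n_vox, sd, phi) {
  if (sd == 0) return(matrix(0, n_t, n_vox))
  eps <- matrix(stats::rnorm(n_t * n_vox, sd = sd), n_t, n_vox)
  if (phi == 0) return(eps)
  # scaling the first innovation makes the zero-init recursion stationary
  eps[1, ] <- eps[1, ] / sqrt(1 - phi^2)
  for (t in 2:n_t) eps[t, ] <- phi * eps[t - 1, ] + eps[t, ]
  eps
}

#' Simulate one subject's task fMRI session
#'
#' For each run the voxel signal is
#' `baseline + sum_conditions pattern(voxel, condition) * regressor(t)
#'  + linear drift + AR(1) Gaussian noise`,
#' where the regressor is the block boxcar convolved with the double-gamma
#' HRF at unit peak, and the pattern is the planted amplitude times the
#' region's condition pattern (zero outside labelled regions).  Per-subject
#' patterns live in the truth object and are reused across runs.
#'
#' @param truth a [phantom_truth()].
#' @param design an `EventTable` covering all runs.
#' @param tr repetition time, s (default 2).
#' @param noise list with `white_sd` (default 1), `ar1` (default 0.3),
#'   `drift_amp` (peak-to-peak linear drift, default 2).
#' @param baseline baseline signal level (default 100, so amplitudes are in
#'   percent-signal-change units).
#' @param hrf an [hrf_params()].
#' @param roi optional 3D logical mask: simulate only the bounding box of
#'   these voxels and return runs cropped to it.  Purely a computational
#'   device for ROI analyses — the signal and noise law of each retained
#'   voxel is identical to the full-grid run, though the particular noise
#'   draws differ.
#' @param seed integer RNG seed.
#' @return List of [bold_run()] objects, one per run, covering the design
#'   plus a 16 s tail.
#' @export
simulate_task_subject <- function(truth, design, tr = 2,
                                  noise = list(white_sd = 1, ar1 = 0.3,
                                               drift_amp = 2),
                                  baseline = 100, hrf = hrf_params(),
                                  roi = NULL, seed = 1) {
  stopifnot(inherits(truth, "PhantomTruth"))
  noise <- utils::modifyList(list(white_sd = 1, ar1 = 0.3, drift_amp = 2), noise)
  if (noise$white_sd < 0) stop("noise white_sd must be >= 0")
  atlas <- truth$atlas
  g <- atlas$grid
  labels <- atlas$labels
  if (!is.null(roi)) {
    box <- bounding_box(roi)
    labels <- crop_volume(labels, box)
    g <- volume_grid(vapply(box, length, integer(1)), g$voxel_size,
                     origin = vox_to_mm(atlas$grid,
                                        vapply(box, min, numeric(1))))
  }
  n_vox <- prod(g$shape)
  runs <- sort(unique(design$run))
  region_roles <- c("semantic_hub", "modality_region",
                    "auditory_spoke", "visual_spoke")
  # pattern vectors are defined over the full region in column-major voxel
  # order; cropping keeps the subset of entries whose voxels survive (the
  # relative order is preserved by column-major subsetting)
  region_idx <- lapply(region_roles,
                       function(r) which(labels == atlas$roles[[r]]))
  names(region_idx) <- region_roles
  pattern_keep <- lapply(region_roles, function(r) {
    full <- which(region_mask(atlas, r))
    if (is.null(roi)) return(seq_along(full))
    co <- arrayInd(full, atlas$grid$shape)
    which(co[, 1] %in% box$x & co[, 2] %in% box$y & co[, 3] %in% box$z)
  })
  names(pattern_keep) <- region_roles

  out <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    ev <- design[design$run == runs[ri], , drop = FALSE]
    n_scans <- ceiling((max(ev$onset + ev$duration) + 16) / tr)
    dm <- build_design_matrix(ev, n_scans = n_scans, tr = tr, hrf = hrf,
                              highpass_cutoff = 0)
    X <- dm$matrix[, dm$task_names, drop = FALSE]
    sig <- matrix(0, n_scans, n_vox)
    for (cond in colnames(X)) {
      for (role in region_roles) {
        if (!length(region_idx[[role]])) next
        pat <- condition_pattern(truth, role, cond)[pattern_keep[[role]]]
        if (!any(pat != 0)) next
        sig[, region_idx[[role]]] <- sig[, region_idx[[role]]] +
          X[, cond, drop = FALSE] %*% rbind(pat)
      }
    }
    run_seed <- stage_seed(seed, sprintf("task_run_%d", runs[ri]))
    out[[ri]] <- with_seed(run_seed, {
      drift <- noise$drift_amp * seq(-0.5, 0.5, length.out = n_scans)
      eps <- ar1_noise(n_scans, n_vox, noise$white_sd, noise$ar1)
      dat <- baseline + sig + drift + eps
      arr <- array(t(dat), dim = c(g$shape, n_scans))
      bold_run(arr, g, tr, motion_params = simulate_motion(n_scans))
    })
  }
  names(out) <- paste0("run", runs)
  out
}
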