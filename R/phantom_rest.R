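# Unit-variance band-limited Gaussian time series (FFT filtering of white
# noise; band in Hz).
bandlimited_series <- function(n_t, tr, band = c(0.01, 0.08)) {
  x <- stats::rnorm(n_t)
  f <- stats::fft(x)
  freqs <- (seq_len(n_t) - 1) / (n_t * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)        # two-sided spectrum
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("frequency band is empty at this run length")
  f[!keep] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n_t
  as.numeric(scale(y))
}

#' Simulate one subject's resting-state run
#'
#' Voxel signal = `baseline + sum_k network_loadings_k * latent_k(t)
#' + confound_loadings * physio(t) + white noise`.  The two latent network
#' time courses are independent band-limited (0.01-0.08 Hz) series with
#' disjoint high-loading territories anchored at the two gray-matter seed
#' regions; the physiological confound (0.01-0.15 Hz) loads strongly on
#' WM/CSF and weakly on gray matter.
#'
#' @param truth a [phantom_truth()].
#' @param n_timepoints number of volumes (default 180, >= 20).
#' @param tr repetition time, s (default 3).
#' @param noise list with `white_sd` (default 1).
#' @param baseline baseline signal level (default 100).
#' @param latent_band,physio_band frequency bands in Hz.
#' @param roi optional 3D logical mask: simulate only the bounding box of
#'   these voxels (same computational device as in
#'   [simulate_task_subject()]).
#' @param seed integer RNG seed.
#' @return A [bold_run()], with attribute `latents` (timepoints x 3 matrix:
#'   network1, network2, physio) for recovery testing.
#' @export
simulate_rest_subject <- function(truth, n_timepoints = 180, tr = 3,
                                  noise = list(white_sd = 1), baseline = 100,
                                  latent_band = c(0.01, 0.08),
                                  physio_band = c(0.01, 0.15), roi = NULL,
                                  seed = 1) {
  stopifnot(inherits(truth, "PhantomTruth"))
  if (n_timepoints < 20) stop("n_timepoints must be >= 20")
  noise <- utils::modifyList(list(white_sd = 1), noise)
  g <- truth$atlas$grid
  loadings <- truth$network_loadings
  confound <- truth$confound_loadings
  if (!is.null(roi)) {
    box <- bounding_box(roi)
    l1 <- crop_volume(loadings[, , , 1], box)
    l2 <- crop_volume(loadings[, , , 2], box)
    loadings <- array(c(l1, l2), dim = c(dim(l1), 2))
    confound <- crop_volume(confound, box)
    g <- volume_grid(vapply(box, length, integer(1)), g$voxel_size,
                     origin = vox_to_mm(truth$atlas$grid,
                                        vapply(box, min, numeric(1))))
  }
  n_vox <- prod(g$shape)
  with_seed(stage_seed(seed, "rest"), {
    lat1 <- bandlimited_series(n_timepoints, tr, latent_band)
    lat2 <- bandlimited_series(n_timepoints, tr, latent_band)
    physio <- bandlimited_series(n_timepoints, tr, physio_band)
    L <- matrix(loadings, nrow = n_vox)   # voxel x 2
    sig <- cbind(lat1, lat2) %*% t(L) +
      physio %*% t(as.numeric(confound))
    if (noise$white_sd > 0)
      sig <- sig + matrix(stats::rnorm(n_timepoints * n_vox,
                                       sd = noise$white_sd),
                          n_timepoints, n_vox)
    arr <- array(t(baseline + sig), dim = c(g$shape, n_timepoints))
    run <- bold_run(arr, g, tr, motion_params = simulate_motion(n_timepoints))
    attr(run, "latents") <- cbind(network1 = lat1, network2 = lat2,
                                  physio = physio)
    run
  })
}
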