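#' Generative ground truth of the phantom
#'
#' Encodes the hub-and-spoke hypothesis as planted multivoxel structure:
#' * the **semantic hub** carries one pattern per semantic feature type
#'   (AUD vs VIS), identical for spoken and written presentation, and no
#'   response to meaningless non-words;
#' * the **modality region** carries one pattern per presentation format
#'   (spoken vs written), identical across AUD/VIS/NON content;
#' * each **sensory spoke** carries both a format and a feature pattern
#'   (summed for word conditions).
#'
#' Pattern vectors are drawn once per truth object, zero-mean and unit-norm
#' within their region.  The truth also fixes the resting-state structure:
#' two latent networks with disjoint high-loading territories (network 1
#' anchored at the modality region + auditory spoke, network 2 at the
#' semantic hub + visual spoke) and a physiological confound loading on
#' WM/CSF (strongly) and gray matter (weakly).
#'
#' @param atlas a [make_phantom_atlas()] result.
#' @param amplitude peak task response in baseline-percent units
#'   (default 2).
#' @param gray_confound_loading physiological confound weight in gray
#'   matter (default 0.4; WM/CSF voxels always load at 1).
#' @param seed integer RNG seed for the pattern draws.
#' @return A `PhantomTruth` list.
#' @export
phantom_truth <- function(atlas, amplitude = 2, gray_confound_loading = 0.4,
                          seed = 1) {
  stopifnot(inherits(atlas, "RegionAtlas"))
  unit_pattern <- function(n) {
    v <- stats::rnorm(n)
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  patterns <- with_seed(stage_seed(seed, "patterns"), {
    n_hub <- sum(region_mask(atlas, "semantic_hub"))
    n_mod <- sum(region_mask(atlas, "modality_region"))
    n_aud <- sum(region_mask(atlas, "auditory_spoke"))
    n_vis <- sum(region_mask(atlas, "visual_spoke"))
    list(
      semantic_hub    = list(AUD = unit_pattern(n_hub), VIS = unit_pattern(n_hub)),
      modality_region = list(Spoken = unit_pattern(n_mod), Written = unit_pattern(n_mod)),
      auditory_spoke  = list(Spoken = unit_pattern(n_aud), Written = unit_pattern(n_aud),
                             AUD = unit_pattern(n_aud), VIS = unit_pattern(n_aud)),
      visual_spoke    = list(Spoken = unit_pattern(n_vis), Written = unit_pattern(n_vis),
                             AUD = unit_pattern(n_vis), VIS = unit_pattern(n_vis)))
  })

  # resting-state loadings
  g <- atlas$grid
  net1 <- region_mask(atlas, "modality_region") | region_mask(atlas, "auditory_spoke")
  net2 <- region_mask(atlas, "semantic_hub") | region_mask(atlas, "visual_spoke")
  network_loadings <- array(0, dim = c(g$shape, 2))
  network_loadings[, , , 1][net1] <- 1
  network_loadings[, , , 2][net2] <- 1
  confound_loadings <- array(0, dim = g$shape)
  confound_loadings[atlas$brain_mask] <- gray_confound_loading
  confound_loadings[region_mask(atlas, "white_matter") |
                    region_mask(atlas, "csf")] <- 1

  structure(list(atlas = atlas, amplitude = amplitude, patterns = patterns,
                 network_loadings = network_loadings,
                 network_masks = list(network1 = net1, network2 = net2),
                 confound_loadings = confound_loadings, seed = seed),
            class = "PhantomTruth")
}

# voxelwise response amplitude of `region` to `condition`, as a vector over
# the region's voxels (zero vector when the region does not respond)
condition_pattern <- function(truth, region, condition) {
  p <- truth$patterns[[region]]
  fmt <- condition_format(condition)
  feat <- condition_feature(condition)
  n <- length(p[[1]])
  out <- numeric(n)
  used <- 0L
  if (fmt %in% names(p)) { out <- out + p[[fmt]]; used <- used + 1L }
  if (feat %in% names(p)) { out <- out + p[[feat]]; used <- used + 1L }
  if (used == 2L) out <- out / sqrt(2)   # keep unit expected norm
  truth$amplitude * out
}
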