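# Simulation studies: canned phantom experiments used for calibration and
# recovery checks.  Each runs the full analysis path (simulate -> GLM ->
# z-score -> searchlight -> group inference) on the default phantom
# geometry and returns the quantities a calibration report needs.

# per-subject task session -> smoothed accuracy maps for the given schemes,
# restricted to `mask` (cropped internally for speed)
.subject_accuracy_maps <- function(truth, mask, schemes, spec, smooth_fwhm,
                                   design_seed, sim_seed,
                                   amplitude_noise = list()) {
  at <- truth$atlas
  design <- generate_block_design(seed = design_seed)
  noise <- utils::modifyList(list(white_sd = 1, ar1 = 0.3, drift_amp = 2),
                             amplitude_noise)
  runs <- simulate_task_subject(truth, design, noise = noise, roi = mask,
                                seed = sim_seed)
  box <- bounding_box(mask)
  cmask <- crop_volume(mask, box)
  fits <- lapply(seq_along(runs), function(r) {
    ev <- design[design$run == r, , drop = FALSE]
    dm <- build_design_matrix(ev, n_scans = dim(runs[[r]]$data)[4], tr = 2,
                              confounds = runs[[r]]$motion_params)
    fit_run_glm(runs[[r]], dm)
  })
  patt <- zscore_patterns(beta_patterns(fits, mask = cmask))
  lapply(schemes, function(sch) {
    am <- searchlight(patt, cmask, spec, sch)
    if (smooth_fwhm > 0) am <- smooth_map(am, fwhm = smooth_fwhm)
    am
  })
}

#' Null-phantom searchlight calibration study
#'
#' Generates label-independent phantom sessions (no condition-dependent
#' pattern is planted: the task amplitude is zero) on the default 28^3
#' geometry, runs the full GLM + z-scoring + cross-modal searchlight path
#' on a compact gray-matter mask, and records each dataset's mean sphere
#' accuracy.  Optionally, null cohorts drawn from these accuracy maps are
#' pushed through the permutation group test to estimate its empirical
#' family-wise error.
#'
#' @param n_datasets number of simulated sessions (default 200).
#' @param scheme_kind classifier scheme to calibrate (default
#'   `"semantic_feature"`).
#' @param n_cohorts number of null cohorts for the FWE estimate (0 skips
#'   it).
#' @param subjects_per_cohort cohort size (default 12).
#' @param n_perm permutations per group test (default 199).
#' @param alpha nominal FWE level (default 0.05).
#' @param smooth_fwhm accuracy-map smoothing in mm (default 6).
#' @param seed master seed.
#' @return List with `mean_accuracy` (per dataset), `overall_mean`,
#'   `se` (standard error of the overall mean over datasets),
#'   `fwe` (proportion of cohorts with any corrected cluster, or NA),
#'   `n_datasets`, `maps` (the per-dataset accuracy maps).
#' @export
null_searchlight_study <- function(n_datasets = 200,
                                   scheme_kind = "semantic_feature",
                                   n_cohorts = 0, subjects_per_cohort = 12,
                                   n_perm = 199, alpha = 0.05,
                                   smooth_fwhm = 6, seed = 1) {
  at <- make_phantom_atlas()
  mask <- region_mask(at, "semantic_hub")
  schemes <- list(make_scheme(scheme_kind))
  spec <- searchlight_spec()
  maps <- vector("list", n_datasets)
  mean_acc <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    truth <- phantom_truth(at, amplitude = 0,
                           seed = stage_seed(seed, sprintf("null_truth_%d", d)))
    am <- .subject_accuracy_maps(
      truth, mask, schemes, spec, smooth_fwhm,
      design_seed = stage_seed(seed, sprintf("null_design_%d", d)),
      sim_seed = stage_seed(seed, sprintf("null_sim_%d", d)))[[1]]
    maps[[d]] <- am
    mean_acc[d] <- mean(am$values[am$valid])
  }
  fwe <- NA_real_
  if (n_cohorts > 0) {
    any_sig <- with_seed(stage_seed(seed, "fwe_cohorts"), {
      vapply(seq_len(n_cohorts), function(cc) {
        pick <- sample(n_datasets, subjects_per_cohort)
        res <- group_chance_test(maps[pick], chance = 0.5, n_perm = n_perm,
                                 seed = stage_seed(seed,
                                                   sprintf("fwe_%d", cc)),
                                 alpha = alpha)
        nrow(res$cluster_table) > 0 && any(res$cluster_table$p_fwe <= alpha)
      }, logical(1))
    })
    fwe <- mean(any_sig)
  }
  list(mean_accuracy = mean_acc, overall_mean = mean(mean_acc),
       se = stats::sd(mean_acc) / sqrt(n_datasets), fwe = fwe,
       n_datasets = n_datasets, maps = maps)
}

#' Dissociation recovery study
#'
#' Simulates a cohort on the default phantom (semantic-feature coding
#' planted in the hub region, presentation-format coding in the modality
#' region), runs both cross-classification searchlights within the joint
#' ROI mask, performs group inference per scheme, and fits the region x
#' classifier dissociation ANOVA.
#'
#' @param n_subjects cohort size (default 12).
#' @param n_perm permutations per group test (default 199).
#' @param alpha corrected significance level (default 0.05).
#' @param seed master seed.
#' @return List with `group` (per-scheme `GroupResult`), `anova`,
#'   `dissociation` table, `rois` (cropped hub/modality masks), `maps`.
#' @export
dissociation_study <- function(n_subjects = 12, n_perm = 199, alpha = 0.05,
                               seed = 1) {
  at <- make_phantom_atlas()
  roi_A <- region_mask(at, "semantic_hub")
  roi_B <- region_mask(at, "modality_region")
  mask <- roi_A | roi_B
  box <- bounding_box(mask)
  schemes <- list(semantic_feature = make_scheme("semantic_feature"),
                  perceptual = make_scheme("perceptual"))
  spec <- searchlight_spec()
  maps <- list(semantic_feature = vector("list", n_subjects),
               perceptual = vector("list", n_subjects))
  for (s in seq_len(n_subjects)) {
    truth <- phantom_truth(at, seed = stage_seed(seed, sprintf("truth_%d", s)))
    ams <- .subject_accuracy_maps(
      truth, mask, schemes, spec, smooth_fwhm = 6,
      design_seed = stage_seed(seed, sprintf("design_%d", s)),
      sim_seed = stage_seed(seed, sprintf("sim_%d", s)))
    maps$semantic_feature[[s]] <- ams$semantic_feature
    maps$perceptual[[s]] <- ams$perceptual
  }
  group <- lapply(names(schemes), function(sch)
    group_chance_test(maps[[sch]], chance = 0.5, n_perm = n_perm,
                      seed = stage_seed(seed, paste0("group_", sch)),
                      alpha = alpha))
  names(group) <- names(schemes)
  rois <- list(vATL_like = crop_volume(roi_A, box),
               aSTG_like = crop_volume(roi_B, box))
  tab <- dissociation_table(maps, rois)
  list(group = group, anova = dissociation_anova(tab), dissociation = tab,
       rois = rois, maps = maps, alpha = alpha)
}

# fraction of `region` voxels inside significant positive clusters
.cluster_coverage <- function(result, region, alpha = 0.05) {
  tab <- result$cluster_table
  if (!nrow(tab)) return(0)
  sig <- tab$label[tab$p_fwe <= alpha]
  if (!length(sig)) return(0)
  hit <- array(result$cluster_labels %in% sig, dim = dim(result$cluster_labels))
  sum(hit & region) / sum(region)
}

#' Seed-contrast connectivity recovery study
#'
#' Simulates a resting cohort on the default phantom, cleans each run with
#' CompCor + motion confound regression and temporal band filtering,
#' computes seed maps from the two network anchor seeds, and tests both
#' paired seed contrasts with cluster-mass permutation correction.  Also
#' returns, per subject, the mean off-network |z| (network-1 seed map
#' inside network-2-exclusive territory) with and without CompCor, to
#' quantify what the nuisance regression buys under the shared
#' physiological confound.
#'
#' @param n_subjects cohort size (default 12).
#' @param n_timepoints rest volumes per subject (default 180).
#' @param n_perm permutations per group test (default 199).
#' @param alpha corrected significance level (default 0.05).
#' @param seed master seed.
#' @return List with `contrast_12`, `contrast_21` (`GroupResult`s for
#'   seed1>seed2 and the reverse), `coverage` (recovered fraction of each
#'   network's exclusive territory), `offnet_z` (data frame: subject,
#'   with_compcor, without_compcor), and the cropped network masks.
#' @export
connectivity_study <- function(n_subjects = 12, n_timepoints = 180,
                               n_perm = 199, alpha = 0.05, seed = 1) {
  at <- make_phantom_atlas()
  wm <- region_mask(at, "white_matter"); csf <- region_mask(at, "csf")
  roi <- at$brain_mask | wm | csf
  box <- bounding_box(roi)
  truth <- phantom_truth(at, seed = stage_seed(seed, "truth"))
  net1 <- crop_volume(truth$network_masks$network1, box)
  net2 <- crop_volume(truth$network_masks$network2, box)
  wm_c <- crop_volume(wm, box); csf_c <- crop_volume(csf, box)
  seed1 <- sphere_roi_mask(vox_to_mm(at$grid, at$centres$modality_region), 3,
                           at$grid, name = "net1_seed")
  seed2 <- sphere_roi_mask(vox_to_mm(at$grid, at$centres$semantic_hub), 3,
                           at$grid, name = "net2_seed")
  seed1_c <- crop_volume(seed1, box); seed2_c <- crop_volume(seed2, box)
  maps1 <- maps2 <- vector("list", n_subjects)
  offnet <- matrix(NA_real_, n_subjects, 2,
                   dimnames = list(NULL, c("with_compcor", "without_compcor")))
  net2_excl <- net2 & !net1 & !seed1_c
  for (s in seq_len(n_subjects)) {
    rest <- simulate_rest_subject(truth, n_timepoints = n_timepoints,
                                  roi = roi,
                                  seed = stage_seed(seed, sprintf("rest_%d", s)))
    cc <- compcor(rest, wm_c, csf_c, k = 5)
    clean <- regress_confounds(rest, cbind(cc, rest$motion_params))
    maps1[[s]] <- seed_map(clean, seed1_c)
    maps2[[s]] <- seed_map(clean, seed2_c)
    plain <- regress_confounds(rest, rest$motion_params)
    m_plain <- seed_map(plain, seed1_c)
    offnet[s, ] <- c(mean(abs(maps1[[s]]$values[net2_excl])),
                     mean(abs(m_plain$values[net2_excl])))
  }
  c12 <- seed_contrast(maps1, maps2, n_perm = n_perm, alpha = alpha,
                       seed = stage_seed(seed, "contrast12"))
  c21 <- seed_contrast(maps2, maps1, n_perm = n_perm, alpha = alpha,
                       seed = stage_seed(seed, "contrast21"))
  coverage <- c(
    network1 = .cluster_coverage(c12, net1 & !net2 & !seed1_c, alpha),
    network2 = .cluster_coverage(c21, net2 & !net1 & !seed2_c, alpha))
  list(contrast_12 = c12, contrast_21 = c21, coverage = coverage,
       offnet_z = data.frame(subject = seq_len(n_subjects),
                             with_compcor = offnet[, 1],
                             without_compcor = offnet[, 2]),
       network_masks = list(network1 = net1, network2 = net2))
}
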