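#' Default demonstration pipeline configuration
#'
#' A compact configuration exercising every stage: a small cohort on the
#' default phantom geometry with reduced permutation counts, suitable for a
#' quick end-to-end run.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `PipelineConfig` list.
#' @export
default_config <- function(out_dir = tempfile("hubspoke_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    phantom = list(shape = 22L, voxel_size = 2, brain_radius_mm = 12,
                   sizes = list(semantic_hub = 60L, modality_region = 60L,
                                auditory_spoke = 30L, visual_spoke = 30L,
                                white_matter = 80L, csf = 40L),
                   amplitude = 2, n_subjects = 6L, n_runs = 4L,
                   reps_per_condition = 1L, block_duration = 20,
                   jitter = c(4, 8), tr_task = 2,
                   noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 2)),
    rest = list(enabled = TRUE, n_timepoints = 120L, tr = 3,
                noise = list(white_sd = 1)),
    glm = list(highpass_cutoff = 0.01),
    searchlight = list(radius = 6, min_voxels = 2, smooth_fwhm = 6),
    group = list(cluster_forming_z = 2.3, n_perm = 199L, alpha = 0.05),
    connectivity = list(seed_radius = 3, compcor_k = 5,
                        band = c(100, 2.8)),
    decode = list(n_terms = 20L, top_k = 15L))
}

#' Run the full phantom-to-decoding pipeline
#'
#' Executes, in order: phantom generation (atlas, truth, block designs,
#' task runs per subject), per-run GLM and beta-pattern extraction,
#' per-run z-scoring, both cross-classification searchlights, accuracy-map
#' smoothing, group inference against chance for each scheme, the region x
#' classifier dissociation ANOVA, then (when enabled) resting-state
#' simulation, CompCor + confound regression, seed maps for the two
#' network anchors, the paired seed contrast, template-network overlap, and
#' meta-analytic decoding of the contrast z-map against synthetic term
#' maps.  All volumes and tables are written under `config$out_dir`
#' together with a JSON manifest recording parameters, seeds and the
#' package version.
#'
#' @param config a [default_config()]-style list.
#' @return Result bundle (invisible): list with `group`, `anova`,
#'   `dissociation`, `connectivity`, `decode`, `manifest`.
#' @export
run_full_pipeline <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[hubspoke] %s", sprintf(...)))
  outputs <- list()
  save_vol <- function(vol, name, grid, datatype = "double") {
    p <- file.path(cfg$out_dir, name)
    write_volume(vol, p, grid = grid, datatype = datatype)
    outputs[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    log_msg("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline halted in stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ph <- cfg$phantom
  atlas <- stage("phantom_atlas",
                 make_phantom_atlas(ph, seed = stage_seed(cfg$seed, "atlas")))
  save_vol(atlas$labels + 0L, "atlas.nii.gz", atlas$grid, datatype = "int32")

  subjects <- seq_len(ph$n_subjects)
  schemes <- list(semantic_feature = make_scheme("semantic_feature"),
                  perceptual = make_scheme("perceptual"))
  spec <- searchlight_spec(radius = cfg$searchlight$radius,
                           min_voxels = cfg$searchlight$min_voxels)
  roi_A <- region_mask(atlas, "semantic_hub")
  roi_B <- region_mask(atlas, "modality_region")
  sl_mask <- roi_A | roi_B

  acc_maps <- list(semantic_feature = list(), perceptual = list())
  stage("task_mvpa", {
    for (s in subjects) {
      truth <- phantom_truth(atlas, amplitude = ph$amplitude,
                             seed = stage_seed(cfg$seed, sprintf("truth_%d", s)))
      design <- generate_block_design(
        n_runs = ph$n_runs, reps_per_condition = ph$reps_per_condition,
        block_duration = ph$block_duration, jitter = ph$jitter,
        seed = stage_seed(cfg$seed, sprintf("design_%d", s)))
      if (s == 1L) {
        p <- file.path(cfg$out_dir, "design_subject1.tsv")
        write_events(design, p)
        outputs[["design_subject1.tsv"]] <- p
      }
      runs <- simulate_task_subject(truth, design, tr = ph$tr_task,
                                    noise = ph$noise,
                                    seed = stage_seed(cfg$seed,
                                                      sprintf("task_%d", s)))
      fits <- lapply(seq_along(runs), function(r) {
        ev <- design[design$run == r, , drop = FALSE]
        dm <- build_design_matrix(ev, n_scans = dim(runs[[r]]$data)[4],
                                  tr = ph$tr_task,
                                  highpass_cutoff = cfg$glm$highpass_cutoff,
                                  confounds = runs[[r]]$motion_params)
        fit_run_glm(runs[[r]], dm)
      })
      patt <- zscore_patterns(beta_patterns(fits, mask = atlas$brain_mask))
      for (sch in names(schemes)) {
        am <- searchlight(patt, sl_mask, spec, schemes[[sch]])
        am <- smooth_map(am, fwhm = cfg$searchlight$smooth_fwhm)
        acc_maps[[sch]][[s]] <- am
        if (s == 1L)
          save_vol(am$values, sprintf("accuracy_%s_subject1.nii.gz", sch),
                   atlas$grid)
      }
    }
  })

  group <- stage("group_inference", {
    lapply(names(schemes), function(sch) {
      g <- group_chance_test(acc_maps[[sch]], chance = 0.5,
                             cluster_forming_z = cfg$group$cluster_forming_z,
                             n_perm = cfg$group$n_perm,
                             seed = stage_seed(cfg$seed, paste0("group_", sch)),
                             alpha = cfg$group$alpha)
      save_vol(g$z_map, sprintf("group_z_%s.nii.gz", sch), atlas$grid)
      p <- file.path(cfg$out_dir, sprintf("clusters_%s.tsv", sch))
      utils::write.table(g$cluster_table, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs[[basename(p)]] <<- p
      g
    }) |> stats::setNames(names(schemes))
  })

  diss <- stage("dissociation_anova", {
    tab <- dissociation_table(acc_maps,
                              rois = list(vATL_like = roi_A, aSTG_like = roi_B))
    list(table = tab, anova = dissociation_anova(tab))
  })

  conn <- decode_res <- NULL
  if (isTRUE(cfg$rest$enabled)) {
    conn <- stage("connectivity", {
      truth0 <- phantom_truth(atlas, amplitude = ph$amplitude,
                              seed = stage_seed(cfg$seed, "truth_rest"))
      seedA <- sphere_roi_mask(vox_to_mm(atlas$grid, atlas$centres$modality_region),
                               cfg$connectivity$seed_radius, atlas$grid,
                               name = "aSTG_like")
      seedB <- sphere_roi_mask(vox_to_mm(atlas$grid, atlas$centres$semantic_hub),
                               cfg$connectivity$seed_radius, atlas$grid,
                               name = "vATL_like")
      wm <- region_mask(atlas, "white_matter")
      csf <- region_mask(atlas, "csf")
      mapsA <- list(); mapsB <- list()
      for (s in subjects) {
        rest <- simulate_rest_subject(truth0,
                                      n_timepoints = cfg$rest$n_timepoints,
                                      tr = cfg$rest$tr, noise = cfg$rest$noise,
                                      seed = stage_seed(cfg$seed,
                                                        sprintf("rest_%d", s)))
        conf <- cbind(compcor(rest, wm, csf, k = cfg$connectivity$compcor_k),
                      rest$motion_params)
        clean <- regress_confounds(rest, conf, band = cfg$connectivity$band)
        mapsA[[s]] <- seed_map(clean, seedA)
        mapsB[[s]] <- seed_map(clean, seedB)
      }
      contrast <- seed_contrast(mapsA, mapsB,
                                cluster_forming_z = cfg$group$cluster_forming_z,
                                n_perm = cfg$group$n_perm,
                                seed = stage_seed(cfg$seed, "group_conn"),
                                alpha = cfg$group$alpha)
      save_vol(contrast$z_map, "contrast_z_aSTGlike_gt_vATLlike.nii.gz",
               atlas$grid)
      templates <- list(network1 = truth0$network_masks$network1,
                        network2 = truth0$network_masks$network2)
      thresh <- !is.na(contrast$z_map) &
        contrast$z_map >= cfg$group$cluster_forming_z
      overlap <- network_overlap(thresh, templates)
      list(contrast = contrast, overlap = overlap,
           maps = list(aSTG_like = mapsA, vATL_like = mapsB))
    })

    decode_res <- stage("decode", {
      zmap <- conn$contrast$z_map
      terms <- synthetic_term_maps(atlas$grid, n_terms = cfg$decode$n_terms,
                                   mask = atlas$brain_mask,
                                   seed = stage_seed(cfg$seed, "terms"))
      dec <- spatial_term_decode(zmap, terms, k = cfg$decode$top_k)
      p <- file.path(cfg$out_dir, "decode_ranking.tsv")
      utils::write.table(rbind(transform(dec$positive, sign = "positive"),
                               transform(dec$negative, sign = "negative")),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[["decode_ranking.tsv"]] <- p
      dec
    })
  } else {
    log_msg("rest data disabled: connectivity and decode stages skipped")
  }

  manifest <- list(
    package = "hubspoke",
    version = as.character(utils::packageVersion("hubspoke")),
    seed = cfg$seed,
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    config = cfg[setdiff(names(cfg), "out_dir")],
    stages_run = c("phantom_atlas", "task_mvpa", "group_inference",
                   "dissociation_anova",
                   if (isTRUE(cfg$rest$enabled)) c("connectivity", "decode")),
    outputs = lapply(outputs, basename))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("done; manifest at %s", manifest_path)
  invisible(list(group = group, anova = diss$anova,
                 dissociation = diss$table, connectivity = conn,
                 decode = decode_res, manifest = manifest,
                 manifest_path = manifest_path, atlas = atlas))
}
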