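#' Fit a per-run voxelwise general linear model
#'
#' Ordinary least squares at every voxel: `betas = (X'X)^-1 X' y`.  The
#' design must be full column rank; rank deficiency is reported with the
#' offending columns named.
#'
#' @param run a [bold_run()].
#' @param design a [build_design_matrix()] result with
#'   `n_scans == dim(run$data)[4]`.
#' @return A `GlmFit`: list with `betas` (4D array, last dim = design
#'   column), `residuals` (4D), `dof`, `design`, `grid`.
#' @export
fit_run_glm <- function(run, design) {
  X <- design$matrix
  n_t <- dim(run$data)[4]
  if (nrow(X) != n_t)
    stop(sprintf("design has %d scans but run has %d volumes", nrow(X), n_t))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- run_matrix(run)                       # time x voxel
  B <- qr.coef(qrX, Y)                       # p x voxel
  R <- Y - X %*% B
  shape <- run$grid$shape
  betas <- array(t(B), dim = c(shape, ncol(X)),
                 dimnames = list(NULL, NULL, NULL, colnames(X)))
  residuals <- array(t(R), dim = c(shape, n_t))
  structure(list(betas = betas, residuals = residuals,
                 dof = n_t - qrX$rank, design = design, grid = run$grid),
            class = "GlmFit")
}

beta_map <- function(fit, column) {
  if (!column %in% dimnames(fit$betas)[[4]])
    stop(sprintf("no design column named '%s'", column))
  fit$betas[, , , column]
}

#' Temporal signal-to-noise ratio map
#'
#' tSNR = temporal mean of the raw signal divided by the standard deviation
#' of the GLM residual time series, per voxel.  Voxels whose residual sd is
#' zero are undefined (NA).  The summary reports, over an optional mask, the
#' mean tSNR and the fraction of defined voxels exceeding a threshold
#' (default 20, a conventional floor for usable signal).
#'
#' @param run a [bold_run()].
#' @param design a design matrix for the run (an intercept-only design is
#'   built when omitted).
#' @param mask optional 3D logical ROI for the summary.
#' @param good_threshold tSNR value counted as "good" (default 20).
#' @return List with `map` (3D, NA where undefined), and `summary`
#'   (`mean`, `fraction_good`, `n_valid`, `all_undefined` flag).
#' @export
tsnr_map <- function(run, design = NULL, mask = NULL, good_threshold = 20) {
  n_t <- dim(run$data)[4]
  if (is.null(design)) {
    X <- matrix(1, n_t, 1, dimnames = list(NULL, "intercept"))
    design <- structure(list(matrix = X, task_names = character(0),
                             confound_names = character(0),
                             n_scans = n_t, tr = run$tr),
                        class = "DesignMatrix")
  }
  fit <- fit_run_glm(run, design)
  Y <- run_matrix(run)
  mu <- colMeans(Y)
  Rm <- fit$residuals
  dim(Rm) <- c(prod(run$grid$shape), n_t)
  sd_res <- col_sds(t(Rm))
  tsnr <- ifelse(sd_res > 0, mu / sd_res, NA_real_)
  map <- array(tsnr, dim = run$grid$shape)
  sel <- if (is.null(mask)) rep(TRUE, length(tsnr)) else as.logical(mask)
  vals <- map[sel]
  valid <- vals[!is.na(vals)]
  structure(list(
    map = map,
    summary = list(mean = if (length(valid)) mean(valid) else NA_real_,
                   fraction_good = if (length(valid)) mean(valid > good_threshold) else NA_real_,
                   n_valid = length(valid),
                   all_undefined = length(valid) == 0L)),
    class = "TsnrMap")
}

#' Percent signal change map for one condition
#'
#' PSC = 100 * beta(condition) * max(condition regressor) / beta(intercept).
#' Task regressors are stored at unit peak, so the beta is the peak response
#' and PSC is that peak as a percentage of baseline.  Voxels where the
#' intercept beta is not positive are undefined (NA).
#'
#' @param fit a [fit_run_glm()] result.
#' @param condition task column name.
#' @return 3D numeric map (NA where undefined).
#' @export
percent_signal_change <- function(fit, condition) {
  if (!condition %in% fit$design$task_names)
    stop(sprintf("condition '%s' is not a task column of this design", condition))
  b <- beta_map(fit, condition)
  b0 <- beta_map(fit, "intercept")
  peak <- max(fit$design$matrix[, condition])
  out <- 100 * b * peak / b0
  out[b0 <= 0] <- NA_real_
  out
}

#' Fixed-effects combination of per-run condition betas
#'
#' Combines runs within a subject as the unweighted mean of per-run betas
#' (with equal-length, identically structured runs this coincides with a
#' variance-weighted fixed-effects average).
#'
#' @param fits list of [fit_run_glm()] results (>= 2) on a shared grid.
#' @param condition task column present in every fit.
#' @return 3D numeric map.
#' @export
fixed_effects_combine <- function(fits, condition) {
  if (length(fits) < 2L) stop("need at least 2 runs to combine")
  g <- fits[[1]]$grid
  for (f in fits[-1])
    if (!same_grid(g, f$grid)) stop("runs do not share a grid")
  maps <- lapply(fits, beta_map, column = condition)
  Reduce(`+`, maps) / length(maps)
}

#' Extract per-run, per-condition beta patterns for MVPA
#'
#' Collects the condition betas of each run into the 5D feature container
#' used by the classifiers: dimensions (x, y, z, run, condition).
#'
#' @param fits list of per-run [fit_run_glm()] results.
#' @param conditions condition columns to extract (default: task columns of
#'   the first fit, sorted to a stable order).
#' @param mask optional 3D logical analysis mask (default all voxels).
#' @return A `BetaPattern`: list with `betas` (5D array), `grid`, `mask`,
#'   `conditions`, `n_runs`, `zscored` flag.
#' @export
beta_patterns <- function(fits, conditions = NULL, mask = NULL) {
  if (!length(fits)) stop("no fits supplied")
  g <- fits[[1]]$grid
  if (is.null(conditions)) conditions <- sort(fits[[1]]$design$task_names)
  for (f in fits) {
    if (!same_grid(g, f$grid)) stop("fits do not share a grid")
    missing <- setdiff(conditions, f$design$task_names)
    if (length(missing))
      stop("condition(s) missing from a run: ", paste(missing, collapse = ", "))
  }
  if (is.null(mask)) mask <- array(TRUE, dim = g$shape)
  n_runs <- length(fits)
  betas <- array(NA_real_, dim = c(g$shape, n_runs, length(conditions)))
  for (r in seq_len(n_runs))
    for (j in seq_along(conditions))
      betas[, , , r, j] <- beta_map(fits[[r]], conditions[j])
  structure(list(betas = betas, grid = g, mask = as.logical(mask) |>
                   array(dim = g$shape),
                 conditions = conditions, n_runs = n_runs, zscored = FALSE),
            class = "BetaPattern")
}
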