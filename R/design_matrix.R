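# Cosine (DCT-II) drift basis implementing the high-pass filter: columns k
# with half-period >= 1/cutoff, i.e. k = 1 .. floor(2 * T * cutoff).
cosine_drift_basis <- function(n_scans, tr, cutoff_hz) {
  if (cutoff_hz <= 0) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  total_t <- n_scans * tr
  n_basis <- floor(2 * total_t * cutoff_hz)
  if (n_basis < 1) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  i <- seq_len(n_scans) - 1
  B <- vapply(seq_len(n_basis),
              function(k) cos(pi * k * (i + 0.5) / n_scans),
              numeric(n_scans))
  colnames(B) <- paste0("drift_", seq_len(n_basis))
  B
}

#' Build a block-design GLM design matrix
#'
#' One boxcar regressor per condition present in the run, convolved with the
#' double-gamma haemodynamic response at a microtime resolution of 16
#' samples per TR, downsampled to scan-onset times, and scaled to unit peak
#' (so a fitted beta is the peak response amplitude in signal units).
#' Temporal high-pass filtering is implemented as cosine drift columns among
#' the confounds; an intercept is always included.
#'
#' @param events an `EventTable` (or data frame) for a single run, with
#'   columns onset, duration, trial_type.
#' @param n_scans number of volumes in the run.
#' @param tr repetition time, s.
#' @param hrf an [hrf_params()] object.
#' @param highpass_cutoff high-pass cutoff in Hz (default 0.01); 0 disables
#'   the drift basis.
#' @param confounds optional numeric matrix/data frame of additional
#'   nuisance regressors (rows = scans), e.g. motion parameters.
#' @return A `DesignMatrix`: list with the numeric `matrix` (named columns),
#'   `task_names`, `confound_names`, `n_scans`, `tr`.
#' @export
build_design_matrix <- function(events, n_scans, tr, hrf = hrf_params(),
                                highpass_cutoff = 0.01, confounds = NULL) {
  check_scalar(tr, "tr", lower = .Machine$double.eps)
  stopifnot(n_scans >= 2)
  ev <- as.data.frame(events)
  if ("run" %in% names(ev) && length(unique(ev$run)) > 1)
    stop("'events' must contain a single run; got runs ",
         paste(unique(ev$run), collapse = ", "))
  run_len <- n_scans * tr
  late <- which(ev$onset + ev$duration > run_len + 1e-9)
  if (length(late))
    stop(sprintf(
      "event '%s' at onset %.2f s (duration %.2f s) extends past the run end (%.2f s)",
      ev$trial_type[late[1]], ev$onset[late[1]], ev$duration[late[1]], run_len))

  micro <- 16L                      # microtime samples per TR
  dt <- tr / micro
  kernel <- double_gamma_hrf(dt, hrf)
  n_micro <- n_scans * micro
  conds <- unique(ev$trial_type)
  task <- matrix(0, nrow = n_scans, ncol = length(conds),
                 dimnames = list(NULL, conds))
  t_micro <- (seq_len(n_micro) - 1) * dt
  scan_idx <- seq(1L, n_micro, by = micro)   # volume-onset samples
  cs <- cumsum(kernel)
  # exact causal convolution of a boxcar with the kernel: running kernel
  # sums between block edges (no FFT round-off before onsets)
  S <- function(x) {
    x <- pmin(x, length(cs))
    out <- numeric(length(x))
    p <- x > 0
    out[p] <- cs[x[p]]
    out
  }
  for (j in seq_along(conds)) {
    conv <- numeric(n_micro)
    sl <- ev[ev$trial_type == conds[j], , drop = FALSE]
    for (b in seq_len(nrow(sl))) {
      occ <- which(t_micro >= sl$onset[b] - 1e-9 &
                   t_micro < sl$onset[b] + sl$duration[b] - 1e-9)
      if (!length(occ)) next
      i <- seq_len(n_micro)
      conv <- conv + S(i - occ[1] + 1L) - S(i - occ[length(occ)])
    }
    reg <- conv[scan_idx]
    mx <- max(reg)
    if (mx <= 0) stop(sprintf("condition '%s' produced an all-zero regressor", conds[j]))
    task[, j] <- reg / mx
  }

  drift <- cosine_drift_basis(n_scans, tr, highpass_cutoff)
  conf <- NULL
  if (!is.null(confounds)) {
    conf <- as.matrix(confounds)
    if (nrow(conf) != n_scans)
      stop("confounds must have one row per scan")
    if (is.null(colnames(conf)))
      colnames(conf) <- paste0("confound_", seq_len(ncol(conf)))
    if (any(!is.finite(conf))) stop("confounds contain non-finite values")
  }
  X <- cbind(task, drift, conf, intercept = 1)
  structure(list(matrix = X, task_names = conds,
                 confound_names = setdiff(colnames(X), c(conds, "intercept")),
                 n_scans = n_scans, tr = tr, hrf = hrf),
            class = "DesignMatrix")
}
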