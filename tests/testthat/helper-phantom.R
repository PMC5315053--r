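# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so individual tests stay fast.

# compact atlas for unit tests (distinct from the full default geometry)
small_atlas <- function(shape = 16L, brain_radius_mm = 10,
                        sizes = list(semantic_hub = 40L, modality_region = 40L,
                                     auditory_spoke = 20L, visual_spoke = 20L,
                                     white_matter = 60L, csf = 30L)) {
  make_phantom_atlas(list(shape = shape, voxel_size = 2,
                          brain_radius_mm = brain_radius_mm, sizes = sizes))
}

# one subject's z-scored beta patterns from a small phantom session
small_patterns <- function(seed = 1, amplitude = 2,
                           noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 2),
                           atlas = small_atlas(), n_runs = 4) {
  truth <- phantom_truth(atlas, amplitude = amplitude, seed = seed)
  design <- generate_block_design(n_runs = n_runs, seed = seed + 1000)
  runs <- simulate_task_subject(truth, design, noise = noise, seed = seed)
  fits <- lapply(seq_along(runs), function(r) {
    ev <- design[design$run == r, , drop = FALSE]
    dm <- build_design_matrix(ev, n_scans = dim(runs[[r]]$data)[4], tr = 2)
    fit_run_glm(runs[[r]], dm)
  })
  list(patterns = zscore_patterns(beta_patterns(fits, mask = atlas$brain_mask)),
       truth = truth, atlas = atlas, design = design, fits = fits)
}

# hand-rolled BetaPattern from an explicit (voxel x run x condition) array,
# for oracle tests that need full control over the features
manual_patterns <- function(values, shape, conditions, zscored = TRUE) {
  n_runs <- dim(values)[2]
  betas <- array(NA_real_, dim = c(shape, n_runs, length(conditions)))
  for (r in seq_len(n_runs))
    for (j in seq_along(conditions))
      betas[, , , r, j] <- array(values[, r, j], dim = shape)
  structure(list(betas = betas, grid = volume_grid(shape, 2),
                 mask = array(TRUE, dim = shape), conditions = conditions,
                 n_runs = n_runs, zscored = zscored),
            class = "BetaPattern")
}

# brute-force sphere offset enumeration, independent of sphere_offsets()
brute_sphere_count <- function(radius, vs) {
  n <- ceiling(radius / min(vs)) + 1
  g <- expand.grid(x = -n:n, y = -n:n, z = -n:n)
  sum((g$x * vs[1])^2 + (g$y * vs[2])^2 + (g$z * vs[3])^2 <= radius^2 + 1e-9)
}

# exact max-margin linear SVM by enumeration over dual active sets
# (KKT system solved per candidate set; feasible solution with the best
# dual objective wins) -- independent oracle for tiny sample counts
qp_svm_oracle <- function(X, y, C = 1) {
  n <- nrow(X)
  K <- X %*% t(X)
  Q <- (y %*% t(y)) * K
  best <- NULL
  states <- expand.grid(rep(list(0:2), n))   # 0: a=0, 1: free, 2: a=C
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    free <- which(st == 1L); atC <- which(st == 2L)
    a <- numeric(n); a[atC] <- C
    if (length(free)) {
      # KKT: Q_ff a_f + y_f b = 1 - Q_fc a_c ; y_f' a_f = -y_c' a_c
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      rhs1 <- rep(1, length(free)) -
        (if (length(atC)) as.numeric(Q[free, atC, drop = FALSE] %*% a[atC])
         else 0)
      rhs <- c(rhs1, -sum(y[atC] * a[atC]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol[seq_along(free)]
      b <- sol[length(sol)]
    } else {
      if (abs(sum(y * a)) > 1e-9) next
      b <- NA_real_
    }
    if (any(a < -1e-9) || any(a > C + 1e-9)) next
    # check KKT signs for bound variables
    g <- as.numeric(Q %*% a) - 1   # dF/da without b term
    if (is.na(b)) {
      # pick b minimising violations
      cand <- -g / y
      b <- stats::median(cand)
    }
    kkt <- g + y * b
    ok <- all(kkt[a < 1e-9] >= -1e-7) &&
      all(abs(kkt[a > 1e-9 & a < C - 1e-9]) < 1e-7) &&
      all(kkt[a > C - 1e-9] <= 1e-7)
    if (!ok) next
    obj <- sum(a) - 0.5 * sum(a * (Q %*% a))
    # KKT-feasible bias interval (a point when free SVs exist):
    # u_i = sum_j a_j y_j K_ij; constraints y_i (u_i + b) >= / = / <= 1
    u <- as.numeric(K %*% (a * y))
    at0 <- a < 1e-9; atCC <- a > C - 1e-9; fr <- !at0 & !atCC
    lo <- max(c(-Inf, (1 - u)[y > 0 & (at0 | fr)],
                (-1 - u)[y < 0 & (atCC | fr)]))
    hi <- min(c(Inf, (1 - u)[y > 0 & (atCC | fr)],
                (-1 - u)[y < 0 & (at0 | fr)]))
    if (is.null(best) || obj > best$obj + 1e-12)
      best <- list(alpha = a, b = b, obj = obj, b_lo = lo, b_hi = hi,
                   w = as.numeric(t(X) %*% (a * y)))
  }
  best
}

expect_no_immediate_repeat <- function(events) {
  for (r in unique(events$run)) {
    sq <- events$trial_type[events$run == r][order(events$onset[events$run == r])]
    expect_false(any(sq[-1] == sq[-length(sq)]))
  }
}
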