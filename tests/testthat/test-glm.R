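test_that("double-gamma kernel starts at zero, peaks at peak_delay, undershoots", {
  h <- double_gamma_hrf(0.01)
  t <- attr(h, "times")
  expect_equal(h[1], 0)
  expect_lt(abs(t[which.max(h)] - 6), 0.5)
  expect_equal(max(h), 1, tolerance = 1e-12)
  late <- h[t > 16]
  expect_true(all(late <= 1e-9))
  expect_lt(min(late), 0)            # a genuine undershoot
  expect_error(hrf_params(peak_delay = -1), "peak_delay")
  expect_error(hrf_params(length = 10), "length")
  expect_error(double_gamma_hrf(0), "tr")
})

test_that("a single block's regressor is causal and returns to baseline", {
  ev <- data.frame(onset = 30, duration = 20, trial_type = "A", run = 1)
  dm <- build_design_matrix(ev, n_scans = 60, tr = 2, highpass_cutoff = 0)
  reg <- dm$matrix[, "A"]
  t <- (seq_len(60) - 1) * 2
  expect_true(all(reg[t < 30] == 0))
  expect_equal(max(reg), 1)
  expect_true(all(abs(reg[t >= 30 + 20 + 30]) < 0.05))
})

test_that("design matrix holds one column per condition plus drift and intercept", {
  des <- generate_block_design(n_runs = 1, seed = 21)
  dm <- build_design_matrix(des, n_scans = 170, tr = 2)
  expect_setequal(dm$task_names, task_conditions())
  expect_true("intercept" %in% colnames(dm$matrix))
  # drift column count equals the brute-force half-period enumeration:
  # cosines k whose period 2T/k is at least 1/cutoff
  T_s <- 170 * 2
  k_ok <- sum(2 * T_s / seq_len(1000) >= 1 / 0.01)
  expect_equal(sum(grepl("^drift_", colnames(dm$matrix))), k_ok)
  expect_equal(k_ok, floor(2 * T_s * 0.01))
  # event past the run end is rejected by name
  bad <- data.frame(onset = 330, duration = 20, trial_type = "Spoken-AUD",
                    run = 1)
  expect_error(build_design_matrix(bad, n_scans = 170, tr = 2), "Spoken-AUD")
})

test_that("HRF convolution matches brute-force discrete summation", {
  params <- hrf_params()
  micro <- 16L
  for (s in 1:100) {
    set.seed(s)
    tr <- sample(c(1, 2, 3), 1)
    n_scans <- 40
    onset <- runif(1, 0, 10)
    dur <- runif(1, 5, 15)
    ev <- data.frame(onset = onset, duration = dur, trial_type = "A", run = 1)
    dm <- build_design_matrix(ev, n_scans = n_scans, tr = tr, hrf = params,
                              highpass_cutoff = 0)
    # oracle: direct O(n^2) convolution at microtime
    dt <- tr / micro
    n_micro <- n_scans * micro
    tm <- (seq_len(n_micro) - 1) * dt
    box <- as.numeric(tm >= onset - 1e-9 & tm < onset + dur - 1e-9)
    k <- double_gamma_hrf(dt, params)
    conv <- numeric(n_micro)
    for (i in seq_len(n_micro)) {
      jj <- seq_len(min(i, length(k)))
      conv[i] <- sum(k[jj] * box[i - jj + 1])
    }
    reg <- conv[seq(1, n_micro, by = micro)]
    reg <- reg / max(reg)
    expect_equal(unname(dm$matrix[, "A"]), reg, tolerance = 1e-10)
  }
})

test_that("voxelwise OLS matches a direct normal-equations solve", {
  set.seed(31)
  for (rep in 1:5) {
    shape <- c(4, 3, 2)
    n_t <- 40
    g <- volume_grid(shape, 2)
    X <- cbind(a = rnorm(n_t), b = rnorm(n_t), intercept = 1)
    Y <- matrix(rnorm(n_t * prod(shape)), n_t)
    run <- bold_run(array(t(Y), dim = c(shape, n_t)), g, 2)
    dm <- structure(list(matrix = X, task_names = c("a", "b"),
                         confound_names = character(0), n_scans = n_t, tr = 2),
                    class = "DesignMatrix")
    fit <- fit_run_glm(run, dm)
    B_oracle <- solve(t(X) %*% X, t(X) %*% Y)
    B_fit <- t(matrix(fit$betas, ncol = 3))
    expect_equal(unname(B_fit), unname(B_oracle), tolerance = 1e-10)
    expect_equal(fit$dof, n_t - 3L)
    # residuals orthogonal to every design column
    R <- t(matrix(fit$residuals, ncol = n_t))
    expect_lt(max(abs(t(X) %*% R)) / sqrt(sum(Y^2)), 1e-6)
  }
})

test_that("noiseless phantom betas are recovered exactly", {
  at <- small_atlas()
  truth <- phantom_truth(at, amplitude = 1.7, seed = 41)
  des <- generate_block_design(seed = 42)
  runs <- simulate_task_subject(truth, des,
                                noise = list(white_sd = 0, ar1 = 0,
                                             drift_amp = 0), seed = 43)
  ev <- des[des$run == 1, ]
  dm <- build_design_matrix(ev, n_scans = dim(runs[[1]]$data)[4], tr = 2)
  fit <- fit_run_glm(runs[[1]], dm)
  hub <- which(region_mask(at, "semantic_hub"))
  planted <- hubspoke:::condition_pattern(truth, "semantic_hub", "Spoken-AUD")
  expect_lt(max(abs(fit$betas[, , , "Spoken-AUD"][hub] - planted)), 1e-8)
  # percent signal change equals the planted amplitude in baseline units
  psc <- percent_signal_change(fit, "Spoken-AUD")
  expect_lt(max(abs(psc[hub] - planted)), 1e-6)
})

test_that("adding a constant shifts only the intercept beta", {
  set.seed(51)
  shape <- c(3, 3, 3); n_t <- 30
  g <- volume_grid(shape, 2)
  X <- cbind(a = rnorm(n_t), intercept = 1)
  dm <- structure(list(matrix = X, task_names = "a",
                       confound_names = character(0), n_scans = n_t, tr = 2),
                  class = "DesignMatrix")
  Y <- array(rnorm(prod(shape) * n_t), dim = c(shape, n_t))
  f1 <- fit_run_glm(bold_run(Y, g, 2), dm)
  f2 <- fit_run_glm(bold_run(Y + 5, g, 2), dm)
  expect_equal(f2$betas[, , , "a"], f1$betas[, , , "a"], tolerance = 1e-10)
  expect_equal(f2$betas[, , , "intercept"],
               f1$betas[, , , "intercept"] + 5, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  n_t <- 20
  X <- cbind(a = rnorm(n_t), intercept = 1)
  X <- cbind(X, dup = X[, "a"])
  dm <- structure(list(matrix = X, task_names = c("a", "dup"),
                       confound_names = character(0), n_scans = n_t, tr = 2),
                  class = "DesignMatrix")
  g <- volume_grid(c(2, 2, 2), 2)
  run <- bold_run(array(rnorm(8 * n_t), dim = c(2, 2, 2, n_t)), g, 2)
  expect_error(fit_run_glm(run, dm), "dup|a")
})

test_that("tSNR estimates mean/sd and is scale invariant", {
  set.seed(61)
  shape <- c(2, 2, 2); n_t <- 10000
  g <- volume_grid(shape, 2)
  Y <- array(100 + rnorm(prod(shape) * n_t), dim = c(shape, n_t))
  ts <- tsnr_map(bold_run(Y, g, 2))
  expect_true(all(ts$map > 97 & ts$map < 103))
  expect_equal(ts$summary$fraction_good, 1)
  # scale invariance
  ts10 <- tsnr_map(bold_run(Y * 10, g, 2))
  expect_equal(ts10$map, ts$map, tolerance = 1e-10)
  # noiseless run: every voxel undefined, flagged summary
  Yc <- array(100, dim = c(shape, 5))
  tsc <- tsnr_map(bold_run(Yc, g, 2))
  expect_true(all(is.na(tsc$map)))
  expect_true(tsc$summary$all_undefined)
  expect_equal(tsc$summary$n_valid, 0L)
})

test_that("percent signal change is linear and zero at zero beta", {
  at <- small_atlas()
  des <- generate_block_design(seed = 71)
  quiet <- list(white_sd = 0, ar1 = 0, drift_amp = 0)
  f_for <- function(amp) {
    truth <- phantom_truth(at, amplitude = amp, seed = 72)
    runs <- simulate_task_subject(truth, des, noise = quiet, seed = 73)
    ev <- des[des$run == 1, ]
    dm <- build_design_matrix(ev, n_scans = dim(runs[[1]]$data)[4], tr = 2)
    fit_run_glm(runs[[1]], dm)
  }
  fit1 <- f_for(1); fit2 <- f_for(2)
  hub <- which(region_mask(at, "semantic_hub"))
  p1 <- percent_signal_change(fit1, "Written-VIS")
  p2 <- percent_signal_change(fit2, "Written-VIS")
  expect_equal(p2[hub], 2 * p1[hub], tolerance = 1e-8)
  # outside every region the response is zero
  bg <- which(at$labels == 0 & !at$brain_mask)[1:50]
  expect_equal(p1[bg], rep(0, 50), tolerance = 1e-8)
  expect_error(percent_signal_change(fit1, "nope"), "not a task column")
})

test_that("fixed-effects combination averages run betas", {
  at <- small_atlas()
  truth <- phantom_truth(at, amplitude = 1.2, seed = 81)
  des <- generate_block_design(seed = 82)
  runs <- simulate_task_subject(truth, des,
                                noise = list(white_sd = 0, ar1 = 0,
                                             drift_amp = 0), seed = 83)
  fits <- lapply(1:4, function(r) {
    ev <- des[des$run == r, ]
    dm <- build_design_matrix(ev, n_scans = dim(runs[[r]]$data)[4], tr = 2)
    fit_run_glm(runs[[r]], dm)
  })
  comb <- fixed_effects_combine(fits, "Spoken-VIS")
  hub <- which(region_mask(at, "semantic_hub"))
  planted <- hubspoke:::condition_pattern(truth, "semantic_hub", "Spoken-VIS")
  expect_lt(max(abs(comb[hub] - planted)), 1e-8)
  # identical runs: mean is idempotent
  expect_equal(fixed_effects_combine(list(fits[[1]], fits[[1]]), "Spoken-VIS"),
               fits[[1]]$betas[, , , "Spoken-VIS"])
  # b and -b cancel
  f_neg <- fits[[2]]
  f_neg$betas <- -f_neg$betas
  z <- fixed_effects_combine(list(fits[[2]], f_neg), "Spoken-VIS")
  expect_equal(max(abs(z)), 0)
  expect_error(fixed_effects_combine(fits[1], "Spoken-VIS"), "at least 2")
})
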