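test_that("z-scoring centres and scales each voxel within each run", {
  set.seed(91)
  vals <- array(rnorm(20 * 2 * 6, mean = 3, sd = 2), dim = c(20, 2, 6))
  p <- manual_patterns(vals, shape = c(5, 2, 2), conditions = task_conditions(),
                       zscored = FALSE)
  z <- zscore_patterns(p)
  for (r in 1:2) {
    M <- matrix(z$betas[, , , r, ], nrow = 20)
    expect_lt(max(abs(rowMeans(M))), 1e-10)
    expect_lt(max(abs(apply(M, 1, sd) - 1)), 1e-10)
  }
  # idempotence
  z2 <- zscore_patterns(z)
  expect_equal(z2$betas, z$betas, tolerance = 1e-12)
  # constant voxel -> zero and flagged
  vals[3, 1, ] <- 7
  pz <- zscore_patterns(manual_patterns(vals, c(5, 2, 2), task_conditions(),
                                        zscored = FALSE))
  M <- matrix(pz$betas[, , , 1, ], nrow = 20)
  expect_equal(unname(M[3, ]), rep(0, 6))
  expect_true(array(pz$flagged[, , , 1], dim = 20)[3])
  # single condition rejected
  one <- manual_patterns(vals[, , 1, drop = FALSE], c(5, 2, 2), "Spoken-AUD",
                         zscored = FALSE)
  expect_error(zscore_patterns(one), "at least 2")
})

test_that("sphere offsets match brute-force lattice enumeration", {
  expect_equal(nrow(sphere_offsets(6, 2)), brute_sphere_count(6, c(2, 2, 2)))
  expect_equal(nrow(sphere_offsets(6, 2)), 123L)
  expect_equal(nrow(sphere_offsets(6, 3)), brute_sphere_count(6, c(3, 3, 3)))
  expect_equal(nrow(sphere_offsets(6, 3)), 33L)
  expect_equal(nrow(sphere_offsets(0, 2)), 1L)
  expect_equal(unname(sphere_offsets(0, 2)[1, ]), c(0L, 0L, 0L))
  # anisotropic voxels honour mm distances
  expect_equal(nrow(sphere_offsets(6, c(2, 3, 4))),
               brute_sphere_count(6, c(2, 3, 4)))
  # deterministic lexicographic order
  o <- sphere_offsets(4, 2)
  expect_identical(o, o[order(o[, 1], o[, 2], o[, 3]), ])
})

test_that("classification schemes define disjoint cross-modal directions", {
  sem <- make_scheme("semantic_feature")
  expect_length(sem$directions, 2L)
  per <- make_scheme("perceptual")
  expect_length(per$directions, 1L)
  expect_setequal(names(per$directions[[1]]$train),
                  c("Spoken-NON", "Written-NON"))
  expect_setequal(names(per$directions[[1]]$test),
                  c("Spoken-AUD", "Spoken-VIS", "Written-AUD", "Written-VIS"))
  for (sch in list(sem, per))
    for (d in sch$directions)
      expect_length(intersect(names(d$train), names(d$test)), 0L)
  expect_equal(sem$C, 1)
  expect_error(make_scheme("other"))
})

test_that("linear SVM solves separable cases and respects label symmetry", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- train_linear_svm(X, c("A", "B"), C = 1)
  pred <- predict(m, X)
  expect_equal(as.character(pred), c("A", "B"))
  expect_gt(attr(pred, "decision_values")[1], 0)   # positive side = class A
  # swapping labels negates the decision function
  m2 <- train_linear_svm(X, c("B", "A"), C = 1)
  expect_equal(attr(predict(m2, X), "decision_values"),
               -attr(predict(m, X), "decision_values"), tolerance = 1e-8)
  expect_error(train_linear_svm(X, c("A", "A")), "2 classes")
})

test_that("SMO solution matches the brute-force dual QP oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- 4
    X <- matrix(rnorm(n * 2), n)
    y <- c(1, 1, -1, -1)
    X[y > 0, ] <- X[y > 0, ] + 2        # separable-ish
    oracle <- qp_svm_oracle(X, y, C = 1)
    fit <- train_linear_svm(X, ifelse(y > 0, "a", "b"), C = 1)
    expect_false(is.null(oracle))
    expect_equal(fit$w, oracle$w, tolerance = 1e-4)
    # the bias is unique only when free support vectors exist; otherwise any
    # value in the KKT-feasible interval is optimal
    expect_gte(fit$b, oracle$b_lo - 1e-4)
    expect_lte(fit$b, oracle$b_hi + 1e-4)
  }
})

test_that("SMO agrees with LIBSVM on random non-separable problems", {
  skip_if_not_installed("e1071")
  set.seed(111)
  for (i in 1:20) {
    n <- 8; d <- 5
    X <- matrix(rnorm(n * d), n)
    y <- rep(c("a", "b"), each = 4)
    fit <- train_linear_svm(X, y, C = 1)
    ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- as.numeric(t(ref$coefs) %*% ref$SV)
    b_ref <- -ref$rho
    pos <- strsplit(colnames(attr(predict(ref, X, decision.values = TRUE),
                                  "decision.values")), "/")[[1]][1]
    if (pos != "a") { w_ref <- -w_ref; b_ref <- -b_ref }
    # LIBSVM's own termination tolerance is 1e-3, so agreement is capped there
    expect_equal(fit$w, w_ref, tolerance = 5e-3)
    expect_equal(fit$b, b_ref, tolerance = 5e-3)
    expect_identical(as.character(predict(fit, X)),
                     as.character(predict(ref, X)))
  }
})

test_that("cross-decoding is perfect on a noiseless shared pattern", {
  # identical class pattern across modalities: 2 voxels code AUD vs VIS
  conds <- task_conditions()
  vals <- array(0, dim = c(2, 4, 6))
  for (j in seq_along(conds)) {
    feat <- sub("^.*-", "", conds[j])
    vals[, , j] <- if (feat == "AUD") c(1, -1) else if (feat == "VIS")
      c(-1, 1) else 0
  }
  p <- manual_patterns(vals, c(2, 1, 1), conds)
  sem <- make_scheme("semantic_feature")
  expect_equal(crossval_cross_decode(p, 1:2, sem), 1.0)
})

test_that("fold accounting: semantic 8 evaluations, perceptual 4", {
  p <- manual_patterns(array(rnorm(2 * 4 * 6), dim = c(2, 4, 6)),
                       c(2, 1, 1), task_conditions())
  plan_sem <- hubspoke:::.cv_plan(p, make_scheme("semantic_feature"))
  plan_per <- hubspoke:::.cv_plan(p, make_scheme("perceptual"))
  expect_equal(plan_sem$n_eval, 8L)
  expect_equal(plan_per$n_eval, 4L)
  # each semantic evaluation trains on 3 runs x 2 conditions, tests on 2
  expect_true(all(lengths(plan_sem$train_rows) == 6L))
  expect_true(all(lengths(plan_sem$test_rows) == 2L))
  expect_true(all(lengths(plan_per$train_rows) == 6L))
  expect_true(all(lengths(plan_per$test_rows) == 4L))
  expect_error(crossval_cross_decode(
    manual_patterns(array(rnorm(12), dim = c(1, 1, 6)), c(1, 1, 1),
                    task_conditions()), 1, make_scheme("perceptual")),
    "at least 2 runs")
})

test_that("cross-decoding matches a by-hand fold enumeration", {
  # 2 runs, 2 voxels, hand-built values
  set.seed(121)
  conds <- task_conditions()
  vals <- array(rnorm(2 * 2 * 6), dim = c(2, 2, 6))
  p <- manual_patterns(vals, c(2, 1, 1), conds)
  sem <- make_scheme("semantic_feature")
  # oracle: enumerate directions x folds manually with the same SVM core
  feats <- function(run, cond) vals[, run, match(cond, conds)]
  accs <- c()
  for (dir in sem$directions) {
    for (held in 1:2) {
      tr_run <- setdiff(1:2, held)
      Xtr <- t(sapply(names(dir$train), function(cc) feats(tr_run, cc)))
      ytr <- unname(dir$train)
      Xte <- t(sapply(names(dir$test), function(cc) feats(held, cc)))
      yte <- unname(dir$test)
      m <- train_linear_svm(Xtr, ytr, C = 1)
      accs <- c(accs, mean(as.character(predict(m, Xte)) == yte))
    }
  }
  expect_equal(crossval_cross_decode(p, 1:2, sem), mean(accs),
               tolerance = 1e-12)
})

test_that("label-independent features decode at chance", {
  set.seed(131)
  accs <- vapply(1:200, function(i) {
    p <- manual_patterns(array(rnorm(10 * 4 * 6), dim = c(10, 4, 6)),
                         c(10, 1, 1), task_conditions())
    crossval_cross_decode(p, 1:10, make_scheme("semantic_feature"))
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-12)
})

test_that("searchlight equals an exhaustive per-voxel oracle", {
  set.seed(141)
  shape <- c(6, 6, 6)
  n_vox <- prod(shape)
  vals <- array(rnorm(n_vox * 4 * 6), dim = c(n_vox, 4, 6))
  p <- manual_patterns(vals, shape, task_conditions())
  mask <- array(runif(n_vox) > 0.3, dim = shape)
  spec <- searchlight_spec(radius = 4, min_voxels = 2)
  sch <- make_scheme("perceptual")
  am <- searchlight(p, mask, spec, sch)
  # oracle: naive loop, independent sphere construction
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  offs <- offs[sqrt(rowSums((offs * 2)^2)) <= 4, ]
  for (v in which(mask)) {
    co <- arrayInd(v, shape)
    pos <- sweep(offs, 2, as.integer(co), "+")
    keep <- apply(pos, 1, function(q) all(q >= 1 & q <= 6) && mask[q[1], q[2], q[3]])
    pos <- pos[keep, , drop = FALSE]
    lin <- pos[, 1] + (pos[, 2] - 1) * 6 + (pos[, 3] - 1) * 36
    if (length(lin) < 2) {
      expect_false(am$valid[v])
    } else {
      expect_equal(am$values[v], crossval_cross_decode(p, lin, sch),
                   tolerance = 1e-12)
    }
  }
  # outside the mask: invalid everywhere
  expect_true(all(is.na(am$values[!mask])))
  expect_false(any(am$valid[!mask]))
})

test_that("searchlight finds planted information only in its region", {
  sp <- small_patterns(seed = 151)
  at <- sp$atlas
  hub <- region_mask(at, "semantic_hub")
  mod <- region_mask(at, "modality_region")
  am <- searchlight(sp$patterns, hub | mod, searchlight_spec(),
                    make_scheme("semantic_feature"))
  expect_gt(roi_mean_accuracy(am, hub), roi_mean_accuracy(am, mod))
})

test_that("smoothing preserves constants, respects validity, matches the kernel", {
  g <- volume_grid(c(21, 21, 21), 2)
  vals <- array(0.7, dim = c(21, 21, 21))
  valid <- array(TRUE, dim = c(21, 21, 21))
  m <- list(values = vals, valid = valid, grid = g)
  sm <- smooth_map(m, fwhm = 6)
  expect_equal(sm$values, vals, tolerance = 1e-10)
  # fwhm 0 is the identity
  expect_identical(smooth_map(m, fwhm = 0)$values, vals)
  # impulse response equals the separable discretised Gaussian
  imp <- array(0, dim = c(21, 21, 21)); imp[11, 11, 11] <- 1
  smi <- smooth_map(list(values = imp, valid = valid, grid = g), fwhm = 6)
  sigma <- 6 / sqrt(8 * log(2)) / 2          # in voxels
  hw <- max(1L, ceiling(3.5 * sigma))
  k1 <- exp(-((-hw:hw)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  oracle <- array(0, dim = c(21, 21, 21))
  for (dx in -hw:hw) for (dy in -hw:hw) for (dz in -hw:hw)
    oracle[11 + dx, 11 + dy, 11 + dz] <-
      k1[dx + hw + 1] * k1[dy + hw + 1] * k1[dz + hw + 1]
  expect_equal(smi$values, oracle, tolerance = 1e-6)
  # invalid voxels neither contribute nor receive
  vals2 <- array(1, dim = c(21, 21, 21)); vals2[11, 11, 11] <- 1000
  valid2 <- valid; valid2[11, 11, 11] <- FALSE
  sm2 <- smooth_map(list(values = vals2, valid = valid2, grid = g), fwhm = 6)
  expect_true(is.na(sm2$values[11, 11, 11]))
  expect_equal(max(abs(sm2$values[valid2] - 1)), 0, tolerance = 1e-10)
})
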