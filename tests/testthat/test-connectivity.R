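test_that("seed sphere masks match brute-force mm geometry", {
  g <- volume_grid(20, 2)
  ctr <- vox_to_mm(g, c(10, 10, 10))
  expect_equal(sum(sphere_roi_mask(ctr, 0.1, g)), 1L)
  # 6 mm diameter seed on the 2 mm grid
  expect_equal(sum(sphere_roi_mask(ctr, 3, g)),
               brute_sphere_count(3, c(2, 2, 2)))
  # translation by one voxel pitch keeps the count
  ctr2 <- vox_to_mm(g, c(11, 10, 10))
  expect_equal(sum(sphere_roi_mask(ctr2, 3, g)),
               sum(sphere_roi_mask(ctr, 3, g)))
  # centre off the lattice with a sub-voxel radius captures nothing
  expect_error(sphere_roi_mask(ctr + 1, 0.1, g), "empty seed")
  expect_error(sphere_roi_mask(c(500, 0, 0), 3, g), "outside")
})

test_that("CompCor recovers a planted physiological component", {
  at <- small_atlas()
  g <- at$grid
  wm <- region_mask(at, "white_matter"); csf <- region_mask(at, "csf")
  n_t <- 120
  set.seed(201)
  physio <- sin(seq(0, 20, length.out = n_t)) + 0.3 * rnorm(n_t)
  Y <- array(rnorm(prod(g$shape) * n_t, sd = 0.1), dim = c(g$shape, n_t))
  idx <- which(wm | csf)
  for (t in seq_len(n_t)) {
    sl <- Y[, , , t]; sl[idx] <- sl[idx] + physio[t]; Y[, , , t] <- sl
  }
  run <- bold_run(Y + 100, g, 3)
  cc <- compcor(run, wm, csf, k = 5)
  expect_gt(abs(cor(cc[, 1], physio)), 0.99)
  # orthonormal component time courses
  expect_equal(crossprod(cc), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # rank-limited request records a warning
  rank2 <- array(0, dim = c(g$shape, n_t))
  b1 <- rnorm(n_t); b2 <- rnorm(n_t)
  for (t in seq_len(n_t)) {
    sl <- rank2[, , , t]
    sl[idx] <- b1[t] + b2[t] * seq_along(idx) / length(idx)
    rank2[, , , t] <- sl
  }
  cc2 <- compcor(bold_run(rank2 + 100, g, 3), wm, csf, k = 5)
  expect_lte(ncol(cc2), 2L)
  expect_match(attr(cc2, "warning"), "rank")
  expect_error(compcor(run, array(FALSE, dim = g$shape),
                       array(FALSE, dim = g$shape), k = 5), "empty")
})

test_that("top eigenvalue share of noise-only compartments matches a simulated null", {
  at <- small_atlas()
  g <- at$grid
  wm <- region_mask(at, "white_matter"); csf <- region_mask(at, "csf")
  n_t <- 60
  n_vox <- sum(wm | csf)
  set.seed(211)
  Y <- array(rnorm(prod(g$shape) * n_t), dim = c(g$shape, n_t)) + 100
  run <- bold_run(Y, g, 3)
  sel <- which(wm | csf)
  Z <- scale(hubspoke:::run_matrix(run)[, sel])
  share_obs <- svd(Z, nu = 0, nv = 0)$d[1]^2 / sum(svd(Z, nu = 0, nv = 0)$d^2)
  # null: same-shape standardised white-noise matrices
  null_share <- vapply(1:50, function(i) {
    M <- scale(matrix(rnorm(n_t * n_vox), n_t))
    d <- svd(M, nu = 0, nv = 0)$d
    d[1]^2 / sum(d^2)
  }, numeric(1))
  expect_gt(share_obs, quantile(null_share, 0.001))
  expect_lt(share_obs, quantile(null_share, 0.999))
})

test_that("confound regression orthogonalises, cleans, and is idempotent", {
  at <- small_atlas()
  truth <- phantom_truth(at, seed = 221)
  rest <- simulate_rest_subject(truth, n_timepoints = 180, seed = 222)
  lat <- attr(rest, "latents")
  conf <- cbind(physio = lat[, "physio"], rest$motion_params)
  clean <- regress_confounds(rest, conf, band = NULL)
  Y <- hubspoke:::run_matrix(clean)
  # residuals orthogonal to each confound column
  Xc <- cbind(1, conf)
  expect_lt(max(abs(crossprod(Xc, Y))) / sqrt(sum(Y^2)), 1e-6)
  # the injected physiological signal no longer correlates anywhere
  r_physio <- abs(cor(lat[, "physio"], Y))
  expect_lt(max(r_physio, na.rm = TRUE), 0.05)
  # idempotence of the projection stage
  clean2 <- regress_confounds(clean, conf, band = NULL)
  expect_equal(clean2$data, clean$data, tolerance = 1e-10)
  # collinear confounds are dropped with a warning
  expect_warning(
    regress_confounds(rest, cbind(a = conf[, 1], b = conf[, 1]), band = NULL),
    "collinear")
})

test_that("seed maps have the Fisher-z null distribution on white noise", {
  g <- volume_grid(c(12, 12, 12), 2)
  n_t <- 180
  set.seed(231)
  Y <- array(rnorm(prod(g$shape) * n_t), dim = c(g$shape, n_t)) + 100
  run <- bold_run(Y, g, 3)
  seed_mask <- array(FALSE, dim = g$shape); seed_mask[6, 6, 6] <- TRUE
  cm <- seed_map(run, seed_mask, name = "probe")
  # the seed voxel itself is flagged and capped
  expect_true(cm$flagged[6, 6, 6])
  expect_equal(cm$values[6, 6, 6], atanh(0.999999))
  z <- cm$values[!cm$flagged]
  # null mean within 3 SE of 0; SE of the mean of ~1727 z values
  n_vox <- length(z)
  expect_lt(abs(mean(z)), 3 * (1 / sqrt(n_t - 3)) / sqrt(n_vox) * 2)
  # null variance within 10% of 1/(n-3)
  expect_lt(abs(var(z) * (n_t - 3) - 1), 0.1)
  expect_error(seed_map(bold_run(array(100, dim = c(2, 2, 2, 10)),
                                 volume_grid(2, 2), 3),
                        array(TRUE, dim = c(2, 2, 2))), "zero variance")
})

test_that("seed maps separate the two planted networks", {
  at <- small_atlas()
  truth <- phantom_truth(at, seed = 241)
  rest <- simulate_rest_subject(truth, n_timepoints = 180, seed = 242)
  conf <- cbind(compcor(rest, region_mask(at, "white_matter"),
                        region_mask(at, "csf"), k = 5),
                rest$motion_params)
  clean <- regress_confounds(rest, conf)
  seed1 <- sphere_roi_mask(vox_to_mm(at$grid, at$centres$modality_region), 3,
                           at$grid, name = "net1_seed")
  cm <- seed_map(clean, seed1)
  net1_only <- truth$network_masks$network1 & !seed1
  net2_only <- truth$network_masks$network2
  tt <- t.test(cm$values[net1_only], cm$values[net2_only])
  expect_gt(mean(cm$values[net1_only]) - mean(cm$values[net2_only]), 0)
  expect_lt(tt$p.value, 0.001)
})

test_that("seed contrasts are antisymmetric and null for identical maps", {
  at <- small_atlas(shape = 10L, brain_radius_mm = 6,
                    sizes = list(semantic_hub = 10L, modality_region = 10L,
                                 auditory_spoke = 5L, visual_spoke = 5L,
                                 white_matter = 15L, csf = 8L))
  g <- at$grid
  set.seed(251)
  mk <- function() {
    v <- array(rnorm(prod(g$shape), sd = 0.3), dim = g$shape)
    list(values = v, valid = array(TRUE, dim = g$shape), grid = g)
  }
  mapsA <- replicate(6, mk(), simplify = FALSE)
  res0 <- seed_contrast(mapsA, mapsA, n_perm = 120, seed = 3)
  expect_equal(nrow(res0$cluster_table), 0L)
  mapsB <- replicate(6, mk(), simplify = FALSE)
  rAB <- seed_contrast(mapsA, mapsB, n_perm = 120, seed = 3)
  rBA <- seed_contrast(mapsB, mapsA, n_perm = 120, seed = 3)
  expect_equal(rAB$z_map, -rBA$z_map, tolerance = 1e-10)
  expect_error(seed_contrast(mapsA, mapsB[1:3]), "pair")
})

test_that("network overlap proportions count voxels exactly", {
  shape <- c(6, 6, 6)
  t1 <- array(FALSE, dim = shape); t1[1:3, , ] <- TRUE
  t2 <- array(FALSE, dim = shape); t2[4:6, , ] <- TRUE
  # map identical to one template
  ov <- network_overlap(t1, list(one = t1, two = t2))
  expect_equal(ov$proportion, c(1, 0))
  # constructed half-and-half split
  half <- array(FALSE, dim = shape); half[3:4, 1, 1] <- TRUE
  ov2 <- network_overlap(half, list(one = t1, two = t2))
  expect_equal(ov2$proportion, c(0.5, 0.5))
  # random map over disjoint templates sums to <= 1
  set.seed(261)
  rnd <- array(runif(prod(shape)) > 0.5, dim = shape)
  ov3 <- network_overlap(rnd, list(one = t1, two = t2))
  expect_lte(sum(ov3$proportion), 1)
  # empty input map is flagged with undefined proportions
  ov4 <- network_overlap(array(FALSE, dim = shape), list(one = t1))
  expect_true(attr(ov4, "empty_map"))
  expect_true(all(is.na(ov4$proportion)))
  expect_equal(ov4$overlap_voxels, 0L)
})
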