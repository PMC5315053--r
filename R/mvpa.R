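#' Z-score beta patterns per voxel within each run
#'
#' For every voxel and run, the values across that run's condition maps are
#' centred to mean 0 and scaled to sd 1 (sample sd).  Voxels with zero
#' variance in a run are set to 0 there and flagged.
#'
#' @param patterns a [beta_patterns()] object with >= 2 conditions.
#' @return The z-scored `BetaPattern`, with `zscored = TRUE` and a logical
#'   `flagged` array (x, y, z, run) marking zero-variance voxels.
#' @export
zscore_patterns <- function(patterns) {
  stopifnot(inherits(patterns, "BetaPattern"))
  n_cond <- length(patterns$conditions)
  if (n_cond < 2L) stop("z-scoring needs at least 2 conditions per run")
  b <- patterns$betas
  dm <- dim(b)
  n_vox <- prod(dm[1:3]); n_runs <- dm[4]
  flagged <- array(FALSE, dim = dm[1:4])
  for (r in seq_len(n_runs)) {
    M <- matrix(b[, , , r, ], nrow = n_vox)       # voxel x condition
    mu <- rowMeans(M)
    sd <- sqrt(rowSums((M - mu)^2) / (n_cond - 1))
    zero <- sd == 0
    sd[zero] <- 1
    Z <- (M - mu) / sd
    Z[zero, ] <- 0
    b[, , , r, ] <- array(Z, dim = c(dm[1:3], n_cond))
    flagged[, , , r] <- array(zero, dim = dm[1:3])
  }
  out <- patterns
  out$betas <- b
  out$zscored <- TRUE
  out$flagged <- flagged
  out
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All voxel offsets whose centre-to-centre Euclidean distance in mm is at
#' most `radius`, including the centre, in lexicographic order.
#'
#' @param radius sphere radius, mm (>= 0).
#' @param voxel_size mm per axis (length 1 or 3).
#' @return Integer matrix with columns dx, dy, dz.
#' @export
sphere_offsets <- function(radius, voxel_size = 2) {
  stopifnot(radius >= 0)
  vs <- as.numeric(voxel_size)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  rng <- lapply(vs, function(v) seq(-floor(radius / v), floor(radius / v)))
  grid <- expand.grid(dz = rng[[3]], dy = rng[[2]], dx = rng[[1]])[, 3:1]
  d2 <- (grid$dx * vs[1])^2 + (grid$dy * vs[2])^2 + (grid$dz * vs[3])^2
  keep <- grid[d2 <= radius^2 + 1e-9, , drop = FALSE]
  keep <- keep[order(keep$dx, keep$dy, keep$dz), ]
  as.matrix(`rownames<-`(keep, NULL))
}

#' Searchlight parameters
#'
#' @param radius sphere radius in mm (default 6).
#' @param min_voxels minimum in-mask sphere size for a valid centre
#'   (default 2).
#' @param chance_level classifier chance level (default 0.5).
#' @return A `SearchlightSpec` list.
#' @export
searchlight_spec <- function(radius = 6, min_voxels = 2, chance_level = 0.5) {
  stopifnot(radius >= 0, min_voxels >= 1,
            chance_level > 0, chance_level < 1)
  structure(list(radius = radius, min_voxels = min_voxels,
                 chance_level = chance_level), class = "SearchlightSpec")
}

#' Construct a cross-classification scheme
#'
#' Two schemes are defined:
#' * `semantic_feature`: decode AUD vs VIS feature words, trained in one
#'   presentation format and tested in the other, in both directions
#'   (spoken->written and written->spoken); accuracies are averaged.
#' * `perceptual`: decode spoken vs written, trained on the non-word
#'   conditions and tested on all four word conditions grouped by format.
#'
#' Within every direction the train and test condition sets are disjoint,
#' so only information shared across the sets can support above-chance
#' accuracy.
#'
#' @param kind `"semantic_feature"` or `"perceptual"`.
#' @param C SVM regularisation parameter (default 1).
#' @return A `ClassifierScheme` list with `name`, `directions` (each a list
#'   with named character vectors `train` and `test` mapping condition ->
#'   class), and `C`.
#' @export
make_scheme <- function(kind = c("semantic_feature", "perceptual"), C = 1) {
  kind <- match.arg(kind)
  stopifnot(C > 0)
  if (kind == "semantic_feature") {
    directions <- list(
      list(train = c("Spoken-AUD" = "AUD", "Spoken-VIS" = "VIS"),
           test  = c("Written-AUD" = "AUD", "Written-VIS" = "VIS")),
      list(train = c("Written-AUD" = "AUD", "Written-VIS" = "VIS"),
           test  = c("Spoken-AUD" = "AUD", "Spoken-VIS" = "VIS")))
  } else {
    directions <- list(
      list(train = c("Spoken-NON" = "Spoken", "Written-NON" = "Written"),
           test  = c("Spoken-AUD" = "Spoken", "Spoken-VIS" = "Spoken",
                     "Written-AUD" = "Written", "Written-VIS" = "Written")))
  }
  for (d in directions)
    if (length(intersect(names(d$train), names(d$test))))
      stop("internal error: train and test condition sets overlap")
  structure(list(name = kind, directions = directions, C = C),
            class = "ClassifierScheme")
}

#' Train a soft-margin linear support vector machine
#'
#' Solves the C-SVM dual by sequential minimal optimisation.  The decision
#' function is `f(x) = x . w + b`; predictions are `sign(f)`, with an exact
#' zero resolved to the first class in sorted label order (and flagged).
#'
#' @param features samples x voxels numeric matrix.
#' @param classes binary labels (factor or character), >= 1 sample each.
#' @param C regularisation parameter (default 1).
#' @return A `LinearSvm` list with `w`, `b`, `classes` (sorted; first is
#'   the positive side... the class predicted for f > 0 is `classes[1]`).
#' @export
train_linear_svm <- function(features, classes, C = 1) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features must be finite")
  cls <- sort(unique(as.character(classes)))
  if (length(cls) != 2L)
    stop(sprintf("need exactly 2 classes, got %d", length(cls)))
  y <- ifelse(as.character(classes) == cls[1], 1L, -1L)
  fit <- .svm_smo(features, as.integer(y), C)
  structure(list(w = as.numeric(fit$w), b = fit$b, classes = cls, C = C,
                 alpha = fit$alpha, iterations = fit$iterations),
            class = "LinearSvm")
}

#' @rdname train_linear_svm
#' @param object a `LinearSvm`.
#' @param newdata samples x voxels matrix.
#' @param ... unused.
#' @export
predict.LinearSvm <- function(object, newdata, ...) {
  dec <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  pred <- ifelse(dec >= 0, object$classes[1], object$classes[2])
  attr(pred, "decision_values") <- dec
  attr(pred, "ties") <- dec == 0
  pred
}

# Map (run, condition) pairs to sample row indices of the flattened feature
# matrix (samples = run-major, condition-minor).
.sample_row <- function(patterns, run, cond) {
  j <- match(cond, patterns$conditions)
  if (anyNA(j)) stop("unknown condition in scheme: ",
                     paste(cond[is.na(j)], collapse = ", "))
  (j - 1L) * patterns$n_runs + run
}

# Build the fold x direction evaluation plan shared by crossval and
# searchlight: integer row indices into the (run x condition) sample stack
# plus +/-1 labels (+1 = first sorted class).
.cv_plan <- function(patterns, scheme) {
  runs <- seq_len(patterns$n_runs)
  plan <- list(train_rows = list(), train_labels = list(),
               test_rows = list(), test_labels = list())
  k <- 0L
  for (dir in scheme$directions) {
    cls <- sort(unique(c(dir$train, dir$test)))
    for (held in runs) {
      k <- k + 1L
      tr_runs <- setdiff(runs, held)
      tr_conds <- rep(names(dir$train), each = length(tr_runs))
      plan$train_rows[[k]] <- .sample_row(patterns,
                                          rep(tr_runs, length(dir$train)),
                                          tr_conds)
      plan$train_labels[[k]] <- ifelse(dir$train[tr_conds] == cls[1], 1L, -1L)
      te_conds <- names(dir$test)
      plan$test_rows[[k]] <- .sample_row(patterns, rep(held, length(te_conds)),
                                         te_conds)
      plan$test_labels[[k]] <- ifelse(dir$test[te_conds] == cls[1], 1L, -1L)
    }
  }
  plan$n_eval <- k
  plan
}

#' Cross-modal leave-one-run-out decoding accuracy
#'
#' For each direction of the scheme and each leave-one-run-out fold, a
#' linear SVM is trained on the direction's train conditions from the
#' training runs and tested on its test conditions from the held-out run.
#' The returned accuracy is the unweighted mean over all fold x direction
#' evaluations.
#'
#' @param patterns a z-scored [beta_patterns()] object with >= 2 runs.
#' @param voxels voxel selection: linear indices into the 3D grid, or a 3D
#'   logical mask.
#' @param scheme a [make_scheme()] object.
#' @return Accuracy proportion in `[0, 1]`.
#' @export
crossval_cross_decode <- function(patterns, voxels, scheme) {
  stopifnot(inherits(patterns, "BetaPattern"), inherits(scheme, "ClassifierScheme"))
  if (patterns$n_runs < 2L) stop("cross-validation needs at least 2 runs")
  if (is.array(voxels) || is.logical(voxels)) voxels <- which(voxels)
  if (!length(voxels)) stop("empty voxel selection")
  dm <- dim(patterns$betas)
  feat <- matrix(patterns$betas, nrow = prod(dm[1:3]))[voxels, , drop = FALSE]
  feat <- t(feat)                           # samples x voxels
  plan <- .cv_plan(patterns, scheme)
  .cv_decode(feat, plan$train_rows, plan$train_labels,
             plan$test_rows, plan$test_labels, scheme$C)
}

#' Spherical searchlight cross-decoding
#'
#' Runs [crossval_cross_decode()] on the in-mask voxels of a sphere centred
#' at every mask voxel, assigning the accuracy to the centre.  Centres
#' whose clipped sphere holds fewer than `spec$min_voxels` voxels are
#' invalid, as is everything outside the mask.
#'
#' @param patterns a z-scored [beta_patterns()] object.
#' @param mask 3D logical analysis mask.
#' @param spec a [searchlight_spec()].
#' @param scheme a [make_scheme()].
#' @return An `AccuracyMap`: list with `values` (3D, NA where invalid),
#'   `valid` (3D logical), `grid`, `spec`, `scheme_name`.
#' @export
searchlight <- function(patterns, mask, spec = searchlight_spec(),
                        scheme = make_scheme("semantic_feature")) {
  stopifnot(inherits(patterns, "BetaPattern"))
  if (!isTRUE(patterns$zscored))
    warning("patterns are not z-scored; searchlight expects zscore_patterns() output")
  g <- patterns$grid
  mask <- array(as.logical(mask), dim = g$shape)
  centers <- which(mask & patterns$mask)
  if (!length(centers)) stop("analysis mask is empty")
  offs <- sphere_offsets(spec$radius, g$voxel_size)
  s <- g$shape
  cidx <- arrayInd(centers, s)
  dm <- dim(patterns$betas)
  feat_all <- matrix(patterns$betas, nrow = prod(s))
  plan <- .cv_plan(patterns, scheme)
  values <- array(NA_real_, dim = s)
  valid <- array(FALSE, dim = s)
  inmask <- mask & patterns$mask
  for (i in seq_along(centers)) {
    pos <- sweep(offs, 2, cidx[i, ], "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= s[1] &
          pos[, 2] >= 1 & pos[, 2] <= s[2] &
          pos[, 3] >= 1 & pos[, 3] <= s[3]
    pos <- pos[ok, , drop = FALSE]
    lin <- pos[, 1] + (pos[, 2] - 1L) * s[1] + (pos[, 3] - 1L) * s[1] * s[2]
    lin <- lin[inmask[lin]]
    if (length(lin) < spec$min_voxels) next
    feat <- t(feat_all[lin, , drop = FALSE])
    values[centers[i]] <- .cv_decode(feat, plan$train_rows, plan$train_labels,
                                     plan$test_rows, plan$test_labels,
                                     scheme$C)
    valid[centers[i]] <- TRUE
  }
  structure(list(values = values, valid = valid, grid = g, spec = spec,
                 scheme_name = scheme$name), class = "AccuracyMap")
}
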