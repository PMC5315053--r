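# Label 26-connected components of a logical 3D array; returns integer
# array (0 = background).  Flood fill over suprathreshold voxels only.
label_clusters <- function(mask3) {
  s <- dim(mask3)
  labels <- array(0L, dim = s)
  idx <- which(mask3)
  if (!length(idx)) return(labels)
  coords <- arrayInd(idx, s)
  key <- idx
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  neigh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  lab <- 0L
  visited <- logical(length(idx))
  for (start in seq_along(idx)) {
    if (visited[start]) next
    lab <- lab + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      labels[idx[cur]] <- lab
      p <- coords[cur, ]
      nb <- sweep(neigh, 2, p, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= s[1] & nb[, 2] >= 1 & nb[, 2] <= s[2] &
            nb[, 3] >= 1 & nb[, 3] <= s[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * s[1] + (nb[, 3] - 1L) * s[1] * s[2]
      for (l in lin) {
        j <- lookup[[as.character(l)]]
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# one-sample t over subject rows -> z map (vector over columns); handles
# zero-variance columns (t = 0 when the mean is 0, +/-Inf capped otherwise)
.t_to_z <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  sd <- col_sds(D)
  tt <- numeric(ncol(D))
  pos <- sd > 0
  tt[pos] <- mu[pos] / (sd[pos] / sqrt(n))
  tt[!pos] <- sign(mu[!pos]) * 38      # beyond any practical threshold
  tt[!pos & mu == 0] <- 0
  z <- numeric(length(tt))
  up <- tt >= 0
  z[up] <- stats::qnorm(stats::pt(tt[up], df = n - 1, lower.tail = FALSE,
                                  log.p = TRUE), log.p = TRUE,
                        lower.tail = FALSE)
  z[!up] <- stats::qnorm(stats::pt(tt[!up], df = n - 1, log.p = TRUE),
                         log.p = TRUE)
  pmin(pmax(z, -38), 38)
}

# cluster masses (sum of z over each suprathreshold cluster)
.cluster_masses <- function(zvec, template, valid_idx, thr) {
  supra <- zvec >= thr
  if (!any(supra)) return(list(masses = numeric(0), labels = NULL))
  m3 <- template
  m3[valid_idx[supra]] <- TRUE
  labs <- label_clusters(m3)
  z3 <- template * 0
  z3[valid_idx] <- zvec
  masses <- tapply(z3[labs > 0], labs[labs > 0], sum)
  list(masses = as.numeric(masses), labels = labs)
}

#' Group inference against chance with cluster-mass permutation FWE
#'
#' Voxelwise one-sample t-test of (value - chance) across subjects,
#' converted to z.  Clusters are formed at `z >= cluster_forming_z`
#' (26-connectivity) and assigned family-wise-error corrected p-values from
#' a sign-flipping permutation null of the maximum cluster mass.
#'
#' @param maps list of >= 5 subject maps (`AccuracyMap`/`ConnectivityMap`
#'   objects or bare 3D arrays) on a shared grid.
#' @param chance null value to test against (0.5 for accuracy maps, 0 for
#'   connectivity contrasts).
#' @param cluster_forming_z cluster-forming threshold (default 2.3).
#' @param n_perm number of sign-flip permutations (default 1000; < 100
#'   records a warning in the parameters).
#' @param seed RNG seed for the permutations.
#' @param alpha significance level recorded for the cluster table
#'   (default 0.05).
#' @return A `GroupResult`: list with `z_map` (3D), `valid`, `cluster_table`
#'   (data frame: label, size, peak mm coordinates, mass, p_fwe),
#'   `cluster_labels` (3D integer), and `parameters`.
#' @export
group_chance_test <- function(maps, chance = 0.5, cluster_forming_z = 2.3,
                              n_perm = 1000, seed = 1, alpha = 0.05) {
  if (length(maps) < 5L) stop("group inference needs at least 5 subjects")
  getv <- function(m) if (is.list(m)) m$values else m
  getval <- function(m) {
    if (is.list(m) && !is.null(m$valid)) m$valid & is.finite(m$values)
    else is.finite(getv(m))
  }
  grid <- if (is.list(maps[[1]])) maps[[1]]$grid else NULL
  s <- dim(getv(maps[[1]]))
  valid <- Reduce(`&`, lapply(maps, getval))
  valid_idx <- which(valid)
  if (!length(valid_idx)) stop("no voxel is valid in every subject")
  D <- t(vapply(maps, function(m) getv(m)[valid_idx] - chance,
                numeric(length(valid_idx))))
  n <- nrow(D)
  warn <- if (n_perm < 100) "n_perm < 100: corrected p-values are coarse" else NULL

  zobs <- .t_to_z(D)
  template <- array(FALSE, dim = s)
  obs <- .cluster_masses(zobs, template, valid_idx, cluster_forming_z)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      zp <- .t_to_z(D * signs)
      mp <- .cluster_masses(zp, template, valid_idx, cluster_forming_z)$masses
      if (length(mp)) max(mp) else 0
    }, numeric(1))
  })

  z_map <- array(NA_real_, dim = s)
  z_map[valid_idx] <- zobs
  labs <- obs$labels
  if (is.null(labs)) labs <- array(0L, dim = s)
  tab <- data.frame(label = integer(0), size = integer(0),
                    peak_x = numeric(0), peak_y = numeric(0),
                    peak_z = numeric(0), mass = numeric(0),
                    p_fwe = numeric(0))
  if (length(obs$masses)) {
    for (l in seq_along(obs$masses)) {
      vox <- which(labs == l)
      peak <- vox[which.max(z_map[vox])]
      pk <- arrayInd(peak, s)
      pk_mm <- if (!is.null(grid)) vox_to_mm(grid, as.numeric(pk)) else as.numeric(pk)
      p <- (1 + sum(null_max >= obs$masses[l])) / (n_perm + 1)
      tab <- rbind(tab, data.frame(label = l, size = length(vox),
                                   peak_x = pk_mm[1], peak_y = pk_mm[2],
                                   peak_z = pk_mm[3],
                                   mass = obs$masses[l], p_fwe = p))
    }
    tab <- tab[order(tab$p_fwe, -tab$size), ]
    rownames(tab) <- NULL
  }
  structure(list(z_map = z_map, valid = valid, cluster_table = tab,
                 cluster_labels = labs,
                 parameters = list(chance = chance,
                                   cluster_forming_z = cluster_forming_z,
                                   n_perm = n_perm, seed = seed,
                                   alpha = alpha, n_subjects = n,
                                   warning = warn)),
            class = "GroupResult")
}

#' Mean accuracy of a map within an ROI
#'
#' @param map an `AccuracyMap` (or compatible list).
#' @param roi 3D logical mask.
#' @return Mean of valid values inside the ROI (NA when none).
#' @export
roi_mean_accuracy <- function(map, roi) {
  sel <- roi & map$valid & is.finite(map$values)
  if (!any(sel)) return(NA_real_)
  mean(map$values[sel])
}
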