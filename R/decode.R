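#' Assemble a term map set for meta-analytic decoding
#'
#' @param maps named list of >= 2 unthresholded 3D maps on a shared grid.
#' @param mask optional 3D logical analysis mask.
#' @return A `TermMapSet` list.
#' @export
term_map_set <- function(maps, mask = NULL) {
  if (length(maps) < 2L) stop("need at least 2 term maps")
  if (is.null(names(maps)) || anyDuplicated(names(maps)))
    stop("term maps must have unique names")
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d)) stop("term maps differ in shape")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("mask shape does not match the term maps")
  structure(list(maps = maps, mask = mask, shape = d), class = "TermMapSet")
}

#' Meta-analytic spatial-correlation decoding
#'
#' Ranks every term map by its Pearson correlation with the input map over
#' the jointly valid voxels, returning the `k` most positively and `k` most
#' negatively correlated terms (ties broken by term name).
#'
#' @param map unthresholded 3D statistic map.
#' @param terms a [term_map_set()].
#' @param k list length per sign (default 15).
#' @param mask optional additional 3D logical mask.
#' @return List with `positive` and `negative` data frames (term, r, rank)
#'   and `all` (every term, sorted by descending r).
#' @export
spatial_term_decode <- function(map, terms, k = 15, mask = NULL) {
  stopifnot(inherits(terms, "TermMapSet"), k >= 1)
  if (!identical(dim(map), terms$shape))
    stop("input map shape does not match the term set")
  valid <- is.finite(map)
  if (!is.null(terms$mask)) valid <- valid & as.logical(terms$mask)
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  for (m in terms$maps) valid <- valid & is.finite(m)
  if (sum(valid) < 10L)
    stop("fewer than 10 jointly valid voxels; cannot correlate")
  x <- map[valid]
  if (stats::sd(x) == 0) stop("input map has zero variance over valid voxels")
  r <- vapply(terms$maps, function(m) {
    y <- m[valid]
    if (stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  tab <- data.frame(term = names(r), r = as.numeric(r),
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$r), , drop = FALSE]
  pos <- tab[order(-tab$r, tab$term), , drop = FALSE]
  neg <- tab[order(tab$r, tab$term), , drop = FALSE]
  kk <- min(k, nrow(tab))
  pos <- pos[seq_len(kk), , drop = FALSE]; pos$rank <- seq_len(kk)
  neg <- neg[seq_len(kk), , drop = FALSE]; neg$rank <- seq_len(kk)
  rownames(pos) <- rownames(neg) <- NULL
  rownames(tab) <- NULL
  list(positive = pos, negative = neg,
       all = tab[order(-tab$r, tab$term), , drop = FALSE],
       n_voxels = sum(valid))
}

#' Generate synthetic orthogonalised term maps
#'
#' Draws `n_terms` smooth random maps on a grid and orthogonalises them
#' (Gram-Schmidt over in-mask voxels), for exercising the decoder without a
#' meta-analytic database.
#'
#' @param grid a [volume_grid()].
#' @param n_terms number of maps (default 50).
#' @param mask optional 3D logical mask.
#' @param fwhm smoothing applied to the raw noise, mm (default 6).
#' @param seed RNG seed.
#' @return A [term_map_set()] with terms named `term_001` ...
#' @export
synthetic_term_maps <- function(grid, n_terms = 50, mask = NULL, fwhm = 6,
                                seed = 1) {
  s <- grid$shape
  if (is.null(mask)) mask <- array(TRUE, dim = s)
  sel <- which(mask)
  if (length(sel) <= n_terms)
    stop("mask too small to orthogonalise this many terms")
  maps <- with_seed(stage_seed(seed, "terms"), {
    B <- matrix(0, nrow = length(sel), ncol = n_terms)
    out <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      raw <- array(stats::rnorm(prod(s)), dim = s)
      sm <- smooth_map(raw, fwhm = fwhm, voxel_size = grid$voxel_size)
      v <- sm[sel]
      v <- v - mean(v)
      if (i > 1) {
        prev <- B[, seq_len(i - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
      B[, i] <- v
      m <- array(NA_real_, dim = s)
      m[sel] <- v
      out[[i]] <- m
    }
    out
  })
  names(maps) <- sprintf("term_%03d", seq_len(n_terms))
  term_map_set(maps, mask = mask)
}
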