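# 1D Gaussian kernel sampled at voxel pitch, truncated at 3.5 sigma,
# normalised to unit sum.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  hw <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# shift a 3D array by `by` voxels along `axis`, zero-filling
shift3 <- function(a, axis, by) {
  if (by == 0) return(a)
  s <- dim(a)
  out <- array(0, dim = s)
  n <- s[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- function(w) switch(axis, `1` = list(w, TRUE, TRUE),
                           `2` = list(TRUE, w, TRUE),
                           `3` = list(TRUE, TRUE, w))
  do.call(`[<-`, c(list(out), ix(dst),
                   list(do.call(`[`, c(list(a), ix(src), list(drop = FALSE))))))
}

conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  hw <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(a))
  for (i in seq_along(kernel))
    out <- out + kernel[i] * shift3(a, axis, i - 1L - hw)
  out
}

#' Validity-aware Gaussian smoothing of a statistic map
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm / sqrt(8 log 2)` mm, renormalised over valid voxels: invalid
#' voxels neither contribute weight nor receive values.
#'
#' @param map an `AccuracyMap` (or any list with `values`, `valid`, `grid`),
#'   or a plain 3D array (then `valid` defaults to finite entries and a
#'   `grid`/`voxel_size` must be supplied).
#' @param fwhm full width at half maximum in mm (0 = identity).
#' @param voxel_size used only when `map` is a bare array.
#' @return Same type as the input with smoothed values.
#' @export
smooth_map <- function(map, fwhm = 6, voxel_size = 2) {
  stopifnot(fwhm >= 0)
  bare <- !is.list(map)
  if (bare) {
    vals <- map
    valid <- is.finite(vals)
    vs <- rep(as.numeric(voxel_size), length.out = 3)
  } else {
    vals <- map$values
    valid <- map$valid & is.finite(vals)
    vs <- map$grid$voxel_size
  }
  if (fwhm == 0) return(map)
  sigma_mm <- fwhm / sqrt(8 * log(2))
  v0 <- vals
  v0[!valid] <- 0
  w <- array(as.numeric(valid), dim = dim(vals))
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / vs[axis])
    v0 <- conv_axis(v0, k, axis)
    w <- conv_axis(w, k, axis)
  }
  out_vals <- array(NA_real_, dim = dim(vals))
  nz <- valid & w > 0
  out_vals[nz] <- v0[nz] / w[nz]
  if (bare) return(out_vals)
  map$values <- out_vals
  map
}
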