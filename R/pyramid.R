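# Multi-resolution image pyramid: Gaussian smoothing + dyadic downsampling.

# separable 1D convolution along the first axis of a 3D array, replicated
# borders
conv_axis1 <- function(arr, k) {
  d <- dim(arr)
  m <- matrix(arr, d[1])
  r <- (length(k) - 1) / 2
  out <- matrix(0, d[1], ncol(m))
  for (j in seq_along(k)) {
    sh <- j - r - 1
    idx <- pmin(pmax(seq_len(d[1]) + sh, 1L), d[1])
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  array(out, d)
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth a volume (separable, sigma in voxels per axis)
#' @param img `image_volume`.
#' @param sigma_vox numeric length-1 or -3, standard deviation in voxels.
#' @export
smooth_gaussian <- function(img, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  a <- img$data
  for (d in 1:3) {
    if (sigma_vox[d] <= 0 || dim(a)[d] < 2) next
    perm <- switch(d, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(conv_axis1(aperm(a, perm), gauss_kernel(sigma_vox[d])), order(perm))
  }
  image_volume(a, img$spacing, img$origin)
}

# level 1 = coarsest of n_levels; level n_levels = native resolution
pyramid_level <- function(img, level, n_levels) {
  fac <- 2^(n_levels - level)
  if (fac == 1) return(img)
  sm <- smooth_gaussian(img, fac / 2)
  d <- dim(sm$data)
  keep <- lapply(1:3, function(a) {
    if (d[a] < 2 * fac) seq_len(d[a]) else seq(1L, d[a], by = fac)
  })
  dat <- sm$data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  sp <- img$spacing * vapply(1:3, function(a) if (length(keep[[a]]) == d[a]) 1 else fac, 1)
  image_volume(dat, sp, img$origin)
}

# central-difference intensity gradient, mm^-1 units, as a list of 3 arrays
gradient_volumes <- function(img) {
  a <- img$data
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    hi <- pmin(seq_len(d[ax]) + 1L, d[ax])
    lo <- pmax(seq_len(d[ax]) - 1L, 1L)
    denom <- (hi - lo) * img$spacing[ax]
    denom[denom == 0] <- 1
    idx_hi <- switch(ax,
      `1` = a[hi, , , drop = FALSE], `2` = a[, hi, , drop = FALSE],
      `3` = a[, , hi, drop = FALSE])
    idx_lo <- switch(ax,
      `1` = a[lo, , , drop = FALSE], `2` = a[, lo, , drop = FALSE],
      `3` = a[, , lo, drop = FALSE])
    rep_den <- switch(ax,
      `1` = array(denom, d),
      `2` = array(rep(denom, each = d[1]), d),
      `3` = array(rep(denom, each = d[1] * d[2]), d))
    g[[ax]] <- (idx_hi - idx_lo) / rep_den
  }
  g
}
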