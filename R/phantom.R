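#' Specification of the synthetic left-atrium phantom
#'
#' The phantom emulates the structure the segmentation method assumes in
#' bright-blood MRA of the left atrium: a large ellipsoidal chamber, four
#' thin tubular pulmonary veins attached at fixed ostia, and a spherical
#' appendage bump, rendered as a bright blood pool with a thin intermediate
#' myocardial rim against a dark background, with additive Gaussian noise
#' and a smooth multiplicative bias field.  Geometry is stylized, not
#' patient-realistic, but reproduces the thin distal tubes far from the
#' chamber centroid where pairwise multi-atlas registration typically
#' degrades.  All randomness is fixed by `seed`.
#'
#' @param shape volume dimensions (voxels).
#' @param spacing voxel size (mm); the default mirrors typical whole-heart
#'   MRA resolution.
#' @param chamber_semiaxes ellipsoid semi-axes (mm) of the LA chamber.
#' @param tube_radius,tube_length pulmonary-vein tube radius and length (mm).
#' @param laa_radius appendage sphere radius (mm).
#' @param rim_thickness myocardial rim thickness (mm).
#' @param intensities named vector `(blood, rim, background)`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (0 disables it).
#' @param deformation_amplitude maximum displacement magnitude (mm) of the
#'   random smooth inter-subject warps; the default approximates residual
#'   anatomical variation after rigid alignment.
#' @param warp_spacing control-point spacing (mm) of the random warps; kept
#'   coarse relative to `deformation_amplitude` so the warps stay
#'   diffeomorphic (coefficients below about 0.4 of the spacing).
#' @param seed integer fixing all randomness.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 64),
                         spacing = c(1.25, 1.25, 2.27),
                         chamber_semiaxes = c(30, 25, 22),
                         tube_radius = 5, tube_length = 25,
                         laa_radius = 8,
                         rim_thickness = 3,
                         intensities = c(blood = 200, rim = 90, background = 30),
                         noise_sigma = 10,
                         bias_amplitude = 0.1,
                         deformation_amplitude = 8,
                         warp_spacing = 25,
                         seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8), all(spacing > 0),
            all(chamber_semiaxes > 0), tube_radius > 0, tube_length > 0,
            laa_radius > 0, noise_sigma >= 0, bias_amplitude >= 0,
            deformation_amplitude >= 0, warp_spacing > 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 chamber_semiaxes = chamber_semiaxes,
                 tube_radius = tube_radius, tube_length = tube_length,
                 laa_radius = laa_radius, rim_thickness = rim_thickness,
                 intensities = intensities, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 deformation_amplitude = deformation_amplitude,
                 warp_spacing = warp_spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

# unit directions (before normalization) and anatomical labels of the four
# pulmonary-vein tubes; left veins exit towards +x, right veins towards -x,
# superior/inferior split along +z/-z
pv_directions <- function() {
  list(LSPV = c(1, 0.35, 0.55), LIPV = c(1, 0.35, -0.55),
       RSPV = c(-1, -0.35, 0.55), RIPV = c(-1, -0.35, -0.55))
}

#' Build the phantom template (undeformed anatomy)
#'
#' Ellipsoidal chamber (label 1), four tubular pulmonary veins attached at
#' fixed ostia on the chamber surface (labels 2-5), a spherical appendage
#' (label 6); voxels keep the first structure that claims them, so the tubes
#' and appendage carry only their extra-chamber parts.  The image is the
#' labelwise intensity rendering plus rim, bias and noise per the spec.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_case`: list with `image` (`image_volume`), `labels`
#'   (`label_volume`) and `generating_transform` (identity for the
#'   template).
#' @export
make_template <- function(spec) {
  set.seed(spec$seed)
  case_from_labels(template_labels(spec), spec, bias_noise = TRUE)
}

template_labels <- function(spec) {
  g <- grid_geometry(spec$shape, spec$spacing)
  pts <- grid_points(g)
  ctr <- image_center(g)
  ax <- spec$chamber_semiaxes
  lab <- integer(nrow(pts))
  xc <- sweep(pts, 2, ctr)
  chamber <- (xc[, 1] / ax[1])^2 + (xc[, 2] / ax[2])^2 + (xc[, 3] / ax[3])^2 <= 1
  lab[chamber] <- 1L
  lm <- la_label_map()
  dirs <- pv_directions()
  for (i in seq_along(dirs)) {
    d <- dirs[[i]] / sqrt(sum(dirs[[i]]^2))
    tfit <- 1 / sqrt(sum((d / ax)^2))       # ellipsoid surface along d
    p0 <- ctr + 0.85 * tfit * d             # ostium slightly inside
    p1 <- p0 + (0.15 * tfit + spec$tube_length) * d
    inside <- capsule_mask(pts, p0, p1, spec$tube_radius)
    lab[inside & lab == 0L] <- lm[[names(dirs)[i]]]
  }
  dl <- c(0.25, -1, 0.45)
  dl <- dl / sqrt(sum(dl^2))
  tfit <- 1 / sqrt(sum((dl / spec$chamber_semiaxes)^2))
  laa_ctr <- ctr + (tfit + 0.45 * spec$laa_radius) * dl
  laa <- rowSums(sweep(pts, 2, laa_ctr)^2) <= spec$laa_radius^2
  lab[laa & lab == 0L] <- lm[["LAA"]]
  lab <- array(lab, spec$shape)
  check_margin(lab, spec)
  label_volume(lab, spec$spacing, origin = c(0, 0, 0))
}

capsule_mask <- function(pts, p0, p1, r) {
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- sweep(pts, 2, p0)
  t <- pmin(pmax((w %*% v) / len2, 0), 1)
  d2 <- rowSums((w - outer(as.vector(t), v))^2)
  d2 <= r^2
}

check_margin <- function(lab, spec, margin_vox = 4L) {
  idx <- which(lab != 0L, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  if (any(lo <= margin_vox) || any(hi > spec$shape - margin_vox))
    stop("phantom geometry overflows the volume (needs a 4-voxel margin)")
  invisible(TRUE)
}

# render image from labels: blood pool, thin myocardial rim, background;
# optionally add the smooth multiplicative bias and Gaussian noise
# (consumes RNG only when used)
case_from_labels <- function(labels, spec, bias_noise = TRUE,
                             generating_transform = composite_transform()) {
  fg <- labels$data != 0L
  dim(fg) <- dim(labels$data)
  d2 <- cpp_edt_sq(fg, dim(fg), labels$spacing)
  rim <- !fg & d2 <= spec$rim_thickness^2
  img <- array(spec$intensities[["background"]], dim(fg))
  img[rim] <- spec$intensities[["rim"]]
  img[fg] <- spec$intensities[["blood"]]
  if (bias_noise && spec$bias_amplitude > 0) {
    img <- img * (1 + spec$bias_amplitude * smooth_random_field(dim(fg)))
  }
  if (bias_noise && spec$noise_sigma > 0) {
    img <- img + rnorm(length(img), sd = spec$noise_sigma)
    dim(img) <- dim(fg)
  }
  structure(list(image = image_volume(img, labels$spacing, labels$origin),
                 labels = labels,
                 generating_transform = generating_transform),
            class = "phantom_case")
}

# coarse random field upsampled trilinearly, scaled to max |.| = 1
smooth_random_field <- function(shp, knots = c(5, 5, 4)) {
  coarse <- array(rnorm(prod(knots)), knots)
  cg <- grid_geometry(knots, spacing = (shp - 1) / pmax(knots - 1, 1))
  idx <- world_to_index(cg, grid_points(grid_geometry(shp)))
  f <- cpp_interp_trilinear(coarse, knots, idx, 0)
  f <- f / max(abs(f))
  array(f, shp)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("phantom_case:\n")
  print(x$image)
  invisible(x)
}

# random smooth B-spline warp over the template domain; spatially correlated
# Gaussian coefficients (smoothed over the lattice) rescaled so the maximum
# displacement magnitude over the domain equals `amplitude` (mm) -- the
# correlation keeps the field gentle enough to stay diffeomorphic
random_warp <- function(geom, amplitude, warp_spacing) {
  bt <- bspline_lattice(geom, warp_spacing)
  cf <- array(rnorm(length(bt$coef)), dim(bt$coef))
  k <- gauss_kernel(1)
  for (d in 1:3) {
    cf <- apply(cf, 4, function(a) {
      perm <- switch(d, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
      aperm(conv_axis1(aperm(a, perm), k), order(perm))
    })
    dim(cf) <- dim(bt$coef)
  }
  bt$coef <- cf
  g <- vol_geometry(geom)
  probe <- grid_geometry(pmax(g$shape %/% 4L, 2L),
                         spacing = g$spacing * (g$shape - 1) /
                           pmax(g$shape %/% 4L - 1L, 1L),
                         origin = g$origin)
  pts <- grid_points(probe)
  mx <- max(sqrt(rowSums((transform_points(bt, pts) - pts)^2)))
  bt$coef <- bt$coef * (amplitude / mx)
  bt
}

#' Generate a synthetic atlas set with known ground truth
#'
#' Produces one target and `n` atlas cases, each obtained by deforming the
#' clean template with an independent random smooth B-spline warp (image and
#' labels share the field), then applying an independent bias field and
#' noise realization.  The generating warps are returned so registration
#' accuracy can be measured against the truth.  Every warp is verified to be
#' invertible (fixed-point inversion residual) before use.
#'
#' @param spec a [phantom_spec()].
#' @param n number of atlases (`>= 2`).
#' @param amplitude_overrides optional numeric vector (length `n`) of
#'   per-atlas deformation amplitudes (mm), e.g. to place some atlases in a
#'   deliberately large-deformation regime.
#' @param warp_spacing_overrides optional per-atlas warp control-point
#'   spacings (mm); large-amplitude warps need a coarser spacing to remain
#'   diffeomorphic.
#' @return List with `target` (a `phantom_case`) and `atlases` (list of `n`
#'   `phantom_case`s).
#' @export
make_atlas_set <- function(spec, n, amplitude_overrides = NULL,
                           warp_spacing_overrides = NULL) {
  if (n < 2) stop("an atlas set needs n >= 2 atlases")
  set.seed(spec$seed)
  amps <- rep(spec$deformation_amplitude, n + 1)
  spac <- rep(spec$warp_spacing, n + 1)
  if (!is.null(amplitude_overrides)) {
    stopifnot(length(amplitude_overrides) == n)
    amps[-1] <- amplitude_overrides
  }
  if (!is.null(warp_spacing_overrides)) {
    stopifnot(length(warp_spacing_overrides) == n)
    spac[-1] <- warp_spacing_overrides
  }
  clean_spec <- spec
  clean_spec$noise_sigma <- 0
  clean_spec$bias_amplitude <- 0
  template <- case_from_labels(template_labels(spec), clean_spec,
                               bias_noise = FALSE)
  geom <- vol_geometry(template$image)
  cshape <- pmax(spec$shape %/% 3L, 12L)
  check_geom <- grid_geometry(cshape,
                              spacing = spec$spacing * (spec$shape - 1) /
                                (cshape - 1L))
  make_case <- function(amp, wspac) {
    if (amp == 0) {
      w <- composite_transform()
      img <- template$image
      lab <- template$labels
    } else {
      w <- random_warp(geom, amp, wspac)
      invisible(invert_transform(w, check_geom, tol = 0.5 * min(spec$spacing),
                                 max_iter = 50))
      # warping the clean rendering keeps partial-volume blending at the
      # deformed boundaries; labels ride the same field (nearest neighbour)
      img <- resample(template$image, w, ref = geom, mode = "linear",
                      fill = spec$intensities[["background"]])
      lab <- resample(template$labels, w, ref = geom, fill = 0)
    }
    dat <- img$data
    if (spec$bias_amplitude > 0)
      dat <- dat * (1 + spec$bias_amplitude * smooth_random_field(dim(dat)))
    if (spec$noise_sigma > 0)
      dat <- dat + array(rnorm(length(dat), sd = spec$noise_sigma), dim(dat))
    structure(list(image = image_volume(dat, img$spacing, img$origin),
                   labels = lab, generating_transform = w),
              class = "phantom_case")
  }
  target <- make_case(amps[1], spac[1])
  atlases <- lapply(seq_len(n), function(i) make_case(amps[i + 1], spac[i + 1]))
  list(target = target, atlases = atlases)
}
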