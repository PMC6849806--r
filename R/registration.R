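#' Registration configuration
#'
#' Settings shared by the pairwise (mutual-information) and joint
#' (variance-over-group) registration modes; both modes consume the same
#' fields wherever applicable so that method comparisons differ only in the
#' optimisation metric.
#'
#' @param n_resolutions number of multi-resolution levels (coarse to fine).
#' @param iterations_per_resolution stochastic gradient descent iterations
#'   per level.
#' @param grid_spacing_mm B-spline control-point spacing sigma (mm) at full
#'   resolution.
#' @param samples_per_iteration random image samples drawn per iteration.
#' @param step_size_schedule named vector `(a, A, alpha)` of the decaying
#'   gain `a * (A / (A + k))^alpha`; `a` is the maximum point displacement
#'   (mm) of the first step.
#' @param seed integer seed fixing all stochastic sampling.
#' @param intensity_range target range `(low, high)` of
#'   [normalize_intensity()]; also the histogram support of the
#'   mutual-information metric.
#' @param mi_bins histogram bins per image for mutual information.
#' @return Object of class `registration_config`.
#' @export
registration_config <- function(n_resolutions = 3,
                                iterations_per_resolution = 1000,
                                grid_spacing_mm = 10,
                                samples_per_iteration = 2048,
                                step_size_schedule = c(a = 1, A = 50, alpha = 0.602),
                                seed = 1L,
                                intensity_range = c(0, 255),
                                mi_bins = 32) {
  stopifnot(n_resolutions >= 1, grid_spacing_mm > 0,
            iterations_per_resolution >= 1, samples_per_iteration >= 16,
            intensity_range[1] < intensity_range[2], mi_bins >= 2)
  sched <- step_size_schedule
  if (is.null(names(sched)) || !all(c("a", "A", "alpha") %in% names(sched)))
    names(sched) <- c("a", "A", "alpha")
  structure(list(n_resolutions = as.integer(n_resolutions),
                 iterations_per_resolution = as.integer(iterations_per_resolution),
                 grid_spacing_mm = grid_spacing_mm,
                 samples_per_iteration = as.integer(samples_per_iteration),
                 step_size_schedule = sched,
                 seed = as.integer(seed),
                 intensity_range = as.numeric(intensity_range),
                 mi_bins = as.integer(mi_bins)),
            class = "registration_config")
}

#' Linearly normalize image intensities to a fixed range
#'
#' Maps `[min(img), max(img)]` onto `range`; a constant image maps to
#' `range[1]`.  Applied to every group member before registration so that
#' intensity variance across the group is meaningful.
#'
#' @param img `image_volume`.
#' @param range numeric `(low, high)`.
#' @export
normalize_intensity <- function(img, range = c(0, 255)) {
  stopifnot(inherits(img, "image_volume"), range[1] < range[2])
  r <- range(img$data)
  d <- if (r[2] > r[1])
    (img$data - r[1]) / (r[2] - r[1]) * (range[2] - range[1]) + range[1]
  else array(range[1], dim(img$data))
  image_volume(d, img$spacing, img$origin)
}

#' Mutual information between two images (bits)
#'
#' Estimated from the joint histogram with `bins` equal-width bins per image
#' over each image's own intensity range.  Symmetric in its arguments and
#' nonnegative up to estimator noise; `MI(X, X) = H(X)`.
#'
#' @param a,b `image_volume`s on a common grid.
#' @param bins histogram bins per image.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, bins = 32) {
  stop_if_grid_mismatch(a, b, "images")
  ia <- hist_bin(a$data, bins)
  ib <- hist_bin(b$data, bins)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, bins, byrow = TRUE))
  pb <- colSums(matrix(p, bins, byrow = TRUE))
  pm <- matrix(p, bins, byrow = TRUE)
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / (pa[row(pm)[nz]] * pb[col(pm)[nz]])))
}

hist_bin <- function(x, bins) {
  r <- range(x)
  if (r[2] <= r[1]) return(rep(1L, length(x)))
  i <- floor((as.vector(x) - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

#' Intensity variance across a group of images
#'
#' The groupwise registration cost: for each voxel, the sum over all group
#' members (target plus atlases) of the squared deviation from the voxelwise
#' group mean, averaged over voxels (a constant factor relative to the plain
#' voxel sum, which leaves the optimum unchanged).
#'
#' @param warped list of `image_volume`s on a common grid, intensity
#'   normalized.
#' @return Scalar variance cost.
#' @export
group_variance <- function(warped) {
  if (!length(warped)) stop("empty image group")
  for (w in warped[-1]) stop_if_grid_mismatch(warped[[1]], w, "group images")
  m <- matrix(unlist(lapply(warped, function(w) as.vector(w$data))),
              ncol = length(warped))
  mu <- rowMeans(m)
  mean(rowSums((m - mu)^2))
}

#' Mean-shape image of a warped group
#'
#' Voxelwise arithmetic mean (weight `1/(N+1)`) of the warped, normalized
#' group members; the average of the group in intensity and -- through the
#' group transforms -- in shape.
#'
#' @param warped list of `image_volume`s on a common grid.
#' @return `image_volume` on the common grid.
#' @export
mean_shape <- function(warped) {
  if (!length(warped)) stop("empty image group")
  for (w in warped[-1]) stop_if_grid_mismatch(warped[[1]], w, "group images")
  acc <- Reduce(`+`, lapply(warped, function(w) w$data)) / length(warped)
  image_volume(acc, warped[[1]]$spacing, warped[[1]]$origin)
}

# ---- internal optimisation machinery ---------------------------------------

sgd_gain <- function(k, sched) {
  unname(sched["a"] * (sched["A"] / (sched["A"] + k))^sched["alpha"])
}

sample_points <- function(geom, n) {
  g <- vol_geometry(geom)
  lo <- g$origin
  hi <- g$origin + (g$shape - 1) * g$spacing
  cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
}

interp_at <- function(arr, geom, pts, fill = NA_real_) {
  cpp_interp_trilinear(arr, dim(arr), world_to_index(geom, pts), fill)
}

euler_zyx_derivs <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3, 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3, 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3, 3)
  list(R = Rz %*% Ry %*% Rx,
       dr1 = Rz %*% Ry %*% dRx,
       dr2 = Rz %*% dRy %*% Rx,
       dr3 = dRz %*% Ry %*% Rx)
}

# affine parameter vector p = (t1, t2, t3, r1, r2, r3, s)
affine_from_par <- function(p, center) {
  affine_transform(translation = p[1:3], rotation = p[4:6], scale = p[7],
                   center = center)
}

# map points and return jacobian pieces for the gradient
affine_apply_par <- function(p, center, pts) {
  der <- euler_zyx_derivs(p[4:6])
  xc <- sweep(pts, 2, center)
  y <- p[7] * (xc %*% t(der$R))
  y <- sweep(y, 2, center + p[1:3], FUN = "+")
  list(y = y, xc = xc, der = der)
}

# gradient of a cost wrt affine params given per-sample dC/dy (n x 3)
affine_param_grad <- function(ap, p, dcdy) {
  xc <- ap$xc; der <- ap$der
  g <- numeric(7)
  g[1:3] <- colSums(dcdy, na.rm = TRUE)
  for (i in 1:3) {
    dy <- p[7] * (xc %*% t(der[[paste0("dr", i)]]))
    g[3 + i] <- sum(dy * dcdy, na.rm = TRUE)
  }
  g[7] <- sum((xc %*% t(der$R)) * dcdy, na.rm = TRUE)
  g
}

affine_step <- function(p, g, gain, L) {
  scales <- c(1, 1, 1, L, L, L, L)
  gs <- g / scales
  m <- max(abs(gs))
  if (!is.finite(m) || m == 0) return(p)
  p - gain * (gs / m) / scales
}

bspline_step <- function(coef, g, gain) {
  m <- max(abs(g))
  if (!is.finite(m) || m == 0) return(coef)
  coef - gain * g / m
}

# light Gaussian smoothing of a lattice gradient (per displacement
# component): damps control-point-scale noise in the stochastic gradient so
# the optimized field stays smooth and diffeomorphic
smooth_lattice_grad <- function(g, sigma = 0.8) {
  k <- gauss_kernel(sigma)
  d4 <- dim(g)
  for (comp in 1:3) {
    a <- g[, , , comp, drop = TRUE]
    dim(a) <- d4[1:3]
    for (ax in 1:3) {
      if (d4[ax] < 2) next
      perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
      a <- aperm(conv_axis1(aperm(a, perm), k), order(perm))
    }
    g[, , , comp] <- a
  }
  g
}

# lattice covering a physical bounding box with full cubic support
lattice_for_bbox <- function(lo, hi, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  lattice_origin <- lo - 2 * sigma
  ncp <- pmax(ceiling((hi - lattice_origin) / sigma) + 3L, 4L)
  bspline_transform(sigma, lattice_origin, ncp = ncp)
}

# bounding box of a geometry's domain mapped through a set of affines,
# padded by pad mm
mapped_bbox <- function(geom, affines, pad = 0) {
  g <- vol_geometry(geom)
  lo <- g$origin
  hi <- g$origin + (g$shape - 1) * g$spacing
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  all_pts <- do.call(rbind, lapply(affines, transform_points, pts = corners))
  list(lo = apply(all_pts, 2, min) - pad, hi = apply(all_pts, 2, max) + pad)
}

image_center <- function(geom) {
  g <- vol_geometry(geom)
  g$origin + (g$shape - 1) * g$spacing / 2
}

half_diagonal <- function(geom) {
  g <- vol_geometry(geom)
  sqrt(sum(((g$shape - 1) * g$spacing / 2)^2))
}

# evaluate B-spline displacement for sample points already mapped by the
# affine; points outside lattice support are flagged NA (dropped from the
# metric rather than aborting a stochastic iteration)
bspline_eval_samples <- function(bt, pts) {
  u <- sweep(sweep(pts, 2, bt$lattice_origin), 2, bt$grid_spacing, FUN = "/")
  ncp <- dim(bt$coef)[1:3]
  ok <- u[, 1] >= 1 & u[, 1] <= ncp[1] - 2 &
        u[, 2] >= 1 & u[, 2] <= ncp[2] - 2 &
        u[, 3] >= 1 & u[, 3] <= ncp[3] - 2
  u[!ok, ] <- 1.5  # dummy inside-support coords; results masked below
  d <- cpp_bspline_disp(bt$coef, ncp, u)
  d[!ok, ] <- NA_real_
  list(y = pts + d, u = u, ok = ok)
}

# ---- pairwise registration -------------------------------------------------

#' Pairwise mutual-information registration
#'
#' Hierarchical (affine, then B-spline free-form) multi-resolution
#' registration of `moving` to `fixed`, maximizing mutual information
#' (the optimizer minimizes `-MI`) by stochastic gradient descent with
#' `samples_per_iteration` random points per step and a Parzen-window
#' (cubic B-spline kernel) histogram for the metric gradient.
#'
#' @param fixed,moving `image_volume`s; the result maps fixed-space points
#'   into moving space (pull-back convention), so
#'   `resample(moving, result, ref = fixed)` aligns `moving` onto `fixed`.
#' @param cfg a [registration_config()].
#' @param stages subset of `c("affine", "bspline")`; the default runs both.
#' @return A [composite_transform()] (affine first, then B-spline), with the
#'   per-iteration objective trace in `attr(, "trace")`.
#' @export
register_pairwise <- function(fixed, moving, cfg = registration_config(),
                              stages = c("affine", "bspline")) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(cfg$seed)
  fN <- normalize_intensity(fixed, cfg$intensity_range)
  mN <- normalize_intensity(moving, cfg$intensity_range)
  R <- cfg$n_resolutions
  center <- image_center(fixed)
  L <- half_diagonal(fixed)
  sched <- cfg$step_size_schedule
  trace <- list()
  p_aff <- c(0, 0, 0, 0, 0, 0, 1)

  lvls <- lapply(seq_len(R), function(l) {
    fl <- pyramid_level(fN, l, R)
    ml <- pyramid_level(mN, l, R)
    list(f = fl, m = ml, gm = gradient_volumes(ml))
  })

  mi_iter <- function(lv, fvals, y, u_ok = NULL) {
    mvals <- interp_at(lv$m$data, lv$m, y)
    gmx <- interp_at(lv$gm[[1]], lv$m, y)
    gmy <- interp_at(lv$gm[[2]], lv$m, y)
    gmz <- interp_at(lv$gm[[3]], lv$m, y)
    res <- cpp_mi_parzen(fvals, mvals, cfg$mi_bins,
                         cfg$intensity_range[1], cfg$intensity_range[2],
                         cfg$intensity_range[1], cfg$intensity_range[2], TRUE)
    w <- -res$grad                      # cost = -MI
    list(cost = -res$mi, dcdy = cbind(w * gmx, w * gmy, w * gmz))
  }

  n_iter <- cfg$iterations_per_resolution
  n_avg <- max(1L, n_iter %/% 4L)   # Polyak tail average damps SGD jitter
  if ("affine" %in% stages) {
    for (l in seq_len(R)) {
      lv <- lvls[[l]]
      acc <- numeric(7)
      for (k in seq_len(n_iter)) {
        pts <- sample_points(lv$f, cfg$samples_per_iteration)
        fvals <- interp_at(lv$f$data, lv$f, pts)
        ap <- affine_apply_par(p_aff, center, pts)
        it <- mi_iter(lv, fvals, ap$y)
        dcdy <- it$dcdy
        dcdy[!is.finite(dcdy)] <- 0
        g <- affine_param_grad(ap, p_aff, dcdy)
        p_aff <- affine_step(p_aff, g, sgd_gain(k - 1, sched), L)
        if (k > n_iter - n_avg) acc <- acc + p_aff
        trace[[length(trace) + 1L]] <- c(1, l, k, it$cost)
      }
      p_aff <- acc / n_avg
    }
  }
  aff <- affine_from_par(p_aff, center)

  bt <- NULL
  if ("bspline" %in% stages) {
    bb <- mapped_bbox(fixed, list(aff), pad = cfg$grid_spacing_mm)
    bt <- lattice_for_bbox(bb$lo, bb$hi, cfg$grid_spacing_mm)
    for (l in seq_len(R)) {
      lv <- lvls[[l]]
      acc <- array(0, dim(bt$coef))
      for (k in seq_len(n_iter)) {
        pts <- sample_points(lv$f, cfg$samples_per_iteration)
        fvals <- interp_at(lv$f$data, lv$f, pts)
        ya <- transform_points(aff, pts)
        bs <- bspline_eval_samples(bt, ya)
        it <- mi_iter(lv, fvals, bs$y)
        r <- it$dcdy
        g <- smooth_lattice_grad(
          cpp_bspline_scatter(dim(bt$coef)[1:3], bs$u, r))
        bt$coef <- bspline_step(bt$coef, g, sgd_gain(k - 1, sched))
        if (k > n_iter - n_avg) acc <- acc + bt$coef
        trace[[length(trace) + 1L]] <- c(2, l, k, it$cost)
      }
      bt$coef <- acc / n_avg
    }
  }

  out <- composite_transform(if (is.null(bt)) list(aff) else list(aff, bt))
  tr <- do.call(rbind, trace)
  attr(out, "trace") <- data.frame(stage = c("affine", "bspline")[tr[, 1]],
                                   level = tr[, 2], iter = tr[, 3],
                                   value = tr[, 4])
  out
}

# ---- joint (groupwise) registration ----------------------------------------

#' Group transform ensemble
#'
#' The joint parameter set of the groupwise registration: one transform per
#' group member, element 1 belonging to the target image and elements
#' `2..N+1` to the atlases, all mapping points of the common (mean-shape)
#' reference grid into the respective image space.
#'
#' @param transforms list of `spatial_transform`s.
#' @param ref_geom the shared reference grid geometry.
#' @export
group_transform_ensemble <- function(transforms, ref_geom) {
  structure(list(transforms = transforms, ref_geom = vol_geometry(ref_geom)),
            class = "group_transform_ensemble")
}

#' @export
print.group_transform_ensemble <- function(x, ...) {
  cat("group_transform_ensemble of", length(x$transforms),
      "transforms (1 target +", length(x$transforms) - 1, "atlases)\n")
  invisible(x)
}

#' Joint-atlas (groupwise) registration
#'
#' Registers the target image and all `N` atlas images in a single
#' optimization over the ensemble of `N + 1` transforms, minimizing the
#' intensity variance over the group ([group_variance()]).  The hierarchy
#' (groupwise affine, then groupwise B-spline), multi-resolution schedule and
#' stochastic gradient descent settings mirror [register_pairwise()].  The
#' gauge freedom of the group objective (a common drift of all transforms
#' leaves the cost unchanged) is fixed by constraining the ensemble mean of
#' the transform parameters to zero after every update.
#'
#' @param target `image_volume` to segment (defines the reference grid of
#'   the mean-shape image).
#' @param atlases list of `N >= 2` `image_volume`s.
#' @param cfg a [registration_config()].
#' @param stages subset of `c("affine", "bspline")`.
#' @return List of class `joint_registration` with elements `ensemble` (a
#'   [group_transform_ensemble()]; element 1 = target), `mean_shape` (an
#'   `image_volume` on the target grid), and `trace`.
#' @export
register_joint <- function(target, atlases, cfg = registration_config(),
                           stages = c("affine", "bspline")) {
  stopifnot(inherits(target, "image_volume"))
  if (length(atlases) < 2) stop("joint registration needs at least 2 atlases")
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(cfg$seed)
  group <- c(list(target), atlases)
  gN <- lapply(group, normalize_intensity, range = cfg$intensity_range)
  J <- length(gN)
  R <- cfg$n_resolutions
  center <- image_center(target)
  L <- half_diagonal(target)
  sched <- cfg$step_size_schedule
  trace <- list()

  lvls <- lapply(seq_len(R), function(l) {
    ref <- pyramid_level(gN[[1]], l, R)   # reference grid = target geometry
    imgs <- lapply(gN, pyramid_level, level = l, n_levels = R)
    grads <- lapply(imgs, gradient_volumes)
    list(ref = ref, imgs = imgs, grads = grads)
  })

  p_aff <- replicate(J, c(0, 0, 0, 0, 0, 0, 1), simplify = FALSE)

  # per-sample intensities and gradients of every member at its warped points
  member_eval <- function(lv, j, y) {
    list(I = interp_at(lv$imgs[[j]]$data, lv$imgs[[j]], y),
         gx = interp_at(lv$grads[[j]][[1]], lv$imgs[[j]], y),
         gy = interp_at(lv$grads[[j]][[2]], lv$imgs[[j]], y),
         gz = interp_at(lv$grads[[j]][[3]], lv$imgs[[j]], y))
  }

  gauge_affine <- function(ps) {
    pm <- Reduce(`+`, ps) / length(ps)
    logs <- vapply(ps, function(p) log(p[7]), 1)
    lapply(ps, function(p) {
      p[1:6] <- p[1:6] - pm[1:6]
      p[7] <- exp(log(p[7]) - mean(logs))
      p
    })
  }

  n_iter <- cfg$iterations_per_resolution
  n_avg <- max(1L, n_iter %/% 4L)
  if ("affine" %in% stages) {
    for (l in seq_len(R)) {
      lv <- lvls[[l]]
      acc <- replicate(J, numeric(7), simplify = FALSE)
      for (k in seq_len(n_iter)) {
        pts <- sample_points(lv$ref, cfg$samples_per_iteration)
        aps <- lapply(seq_len(J), function(j) affine_apply_par(p_aff[[j]], center, pts))
        evs <- lapply(seq_len(J), function(j) member_eval(lv, j, aps[[j]]$y))
        Imat <- vapply(evs, `[[`, numeric(nrow(pts)), "I")
        valid <- rowSums(!is.finite(Imat)) == 0
        nv <- sum(valid)
        if (nv < 16) next
        mu <- rowMeans(Imat)
        resid <- Imat - mu
        cost <- sum(resid[valid, ]^2) / nv
        gain <- sgd_gain(k - 1, sched)
        for (j in seq_len(J)) {
          w <- ifelse(valid, 2 * resid[, j] / nv, 0)
          dcdy <- cbind(w * evs[[j]]$gx, w * evs[[j]]$gy, w * evs[[j]]$gz)
          dcdy[!is.finite(dcdy)] <- 0
          g <- affine_param_grad(aps[[j]], p_aff[[j]], dcdy)
          p_aff[[j]] <- affine_step(p_aff[[j]], g, gain, L)
        }
        p_aff <- gauge_affine(p_aff)
        if (k > n_iter - n_avg)
          acc <- lapply(seq_len(J), function(j) acc[[j]] + p_aff[[j]])
        trace[[length(trace) + 1L]] <- c(1, l, k, cost)
      }
      p_aff <- lapply(acc, `/`, n_avg)
    }
  }
  affs <- lapply(p_aff, affine_from_par, center = center)

  bts <- NULL
  if ("bspline" %in% stages) {
    bb <- mapped_bbox(target, affs, pad = cfg$grid_spacing_mm)
    proto <- lattice_for_bbox(bb$lo, bb$hi, cfg$grid_spacing_mm)
    bts <- replicate(J, proto, simplify = FALSE)
    cdim <- dim(proto$coef)[1:3]
    for (l in seq_len(R)) {
      lv <- lvls[[l]]
      acc <- replicate(J, array(0, dim(proto$coef)), simplify = FALSE)
      for (k in seq_len(n_iter)) {
        pts <- sample_points(lv$ref, cfg$samples_per_iteration)
        bss <- vector("list", J)
        evs <- vector("list", J)
        for (j in seq_len(J)) {
          ya <- transform_points(affs[[j]], pts)
          bss[[j]] <- bspline_eval_samples(bts[[j]], ya)
          evs[[j]] <- member_eval(lv, j, bss[[j]]$y)
        }
        Imat <- vapply(evs, `[[`, numeric(nrow(pts)), "I")
        valid <- rowSums(!is.finite(Imat)) == 0
        nv <- sum(valid)
        if (nv < 16) next
        mu <- rowMeans(Imat)
        resid <- Imat - mu
        cost <- sum(resid[valid, ]^2) / nv
        gain <- sgd_gain(k - 1, sched)
        gsum <- array(0, dim(proto$coef))
        for (j in seq_len(J)) {
          w <- ifelse(valid, 2 * resid[, j] / nv, 0)
          r <- cbind(w * evs[[j]]$gx, w * evs[[j]]$gy, w * evs[[j]]$gz)
          g <- smooth_lattice_grad(cpp_bspline_scatter(cdim, bss[[j]]$u, r))
          bts[[j]]$coef <- bspline_step(bts[[j]]$coef, g, gain)
          gsum <- gsum + bts[[j]]$coef
        }
        gmean <- gsum / J                       # zero-mean displacement gauge
        for (j in seq_len(J)) bts[[j]]$coef <- bts[[j]]$coef - gmean
        if (k > n_iter - n_avg)
          for (j in seq_len(J)) acc[[j]] <- acc[[j]] + bts[[j]]$coef
        trace[[length(trace) + 1L]] <- c(2, l, k, cost)
      }
      for (j in seq_len(J)) bts[[j]]$coef <- acc[[j]] / n_avg
    }
  }

  transforms <- lapply(seq_len(J), function(j)
    composite_transform(if (is.null(bts)) list(affs[[j]])
                        else list(affs[[j]], bts[[j]])))
  ensemble <- group_transform_ensemble(transforms, target)
  warped <- lapply(seq_len(J), function(j)
    resample(gN[[j]], transforms[[j]], ref = target, fill = 0))
  ms <- mean_shape(warped)
  tr <- do.call(rbind, trace)
  structure(list(ensemble = ensemble, mean_shape = ms,
                 trace = data.frame(stage = c("affine", "bspline")[tr[, 1]],
                                    level = tr[, 2], iter = tr[, 3],
                                    value = tr[, 4])),
            class = "joint_registration")
}
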