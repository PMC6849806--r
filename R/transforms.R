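#' Affine transform (translation, ZYX Euler rotation, isotropic scale)
#'
#' Maps a physical point `x` (mm) to
#' `center + scale * R %*% (x - center) + translation`, where
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` (rotations applied about the x axis
#' first, then y, then z: fixed ZYX order).  Rotation and scaling act about
#' `center`, conventionally the image centre.  With zero translation, zero
#' rotation and unit scale the transform is the identity.
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3 Euler angles (rad), order (rx, ry, rz).
#' @param scale single positive scalar (isotropic).
#' @param center numeric length-3 fixed point (mm) of rotation and scaling.
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = 1, center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 1, length(center) == 3)
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 center = as.numeric(center)),
            class = c("affine_transform", "spatial_transform"))
}

euler_zyx_matrix <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' B-spline free-form deformation
#'
#' A displacement field parameterised by 3-vector coefficients `p_k` on a
#' regular control-point lattice with spacing `grid_spacing` (mm):
#' `T(x) = x + sum_k p_k * beta3((x - x_k) / sigma)` with `beta3` the
#' tensor-product cubic B-spline.  The basis has compact support, so the
#' displacement at a point depends only on the surrounding 4 x 4 x 4 control
#' points; with all coefficients zero the transform is the identity.
#' Use [bspline_lattice()] to build a lattice covering an image domain with
#' the required two-control-point margin on every side.
#'
#' @param grid_spacing numeric length-3, control-point spacing sigma (mm).
#' @param lattice_origin numeric length-3, physical position (mm) of control
#'   point `[1, 1, 1]`.
#' @param coef 4D array `(nx, ny, nz, 3)` of coefficient vectors (mm); if
#'   missing, a zero (identity) field of dimensions `ncp` is created.
#' @param ncp integer length-3 lattice size (only needed when `coef` missing).
#' @return Object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_spacing, lattice_origin, coef = NULL,
                              ncp = NULL) {
  grid_spacing <- as.numeric(grid_spacing)
  if (length(grid_spacing) == 1) grid_spacing <- rep(grid_spacing, 3)
  stopifnot(length(grid_spacing) == 3, all(grid_spacing > 0),
            length(lattice_origin) == 3)
  if (is.null(coef)) {
    stopifnot(!is.null(ncp), length(ncp) == 3)
    coef <- array(0, c(as.integer(ncp), 3L))
  }
  if (length(dim(coef)) != 4L || dim(coef)[4] != 3L)
    stop("coef must be an (nx, ny, nz, 3) array")
  if (any(dim(coef)[1:3] < 4L))
    stop("lattice needs at least 4 control points per axis")
  structure(list(grid_spacing = grid_spacing,
                 lattice_origin = as.numeric(lattice_origin),
                 coef = coef),
            class = c("bspline_transform", "spatial_transform"))
}

#' Build a zero B-spline lattice covering an image domain
#'
#' Control points are placed on a regular grid extending at least two points
#' beyond the image bounds per side, so that every point of the domain has
#' full cubic-spline support.
#'
#' @param geom grid geometry (or volume) to cover.
#' @param grid_spacing control-point spacing (mm), scalar or length-3.
#' @return A `bspline_transform` with zero coefficients.
#' @export
bspline_lattice <- function(geom, grid_spacing) {
  g <- vol_geometry(geom)
  if (length(grid_spacing) == 1) grid_spacing <- rep(grid_spacing, 3)
  lo <- g$origin
  hi <- g$origin + (g$shape - 1) * g$spacing
  lattice_origin <- lo - 2 * grid_spacing
  # valid support region is [origin + sigma, origin + (ncp - 2) sigma]
  ncp <- ceiling((hi - lattice_origin) / grid_spacing) + 3L
  bspline_transform(grid_spacing, lattice_origin, ncp = pmax(ncp, 4L))
}

#' Dense displacement-field transform
#'
#' Displacement vectors sampled on a regular grid, applied by trilinear
#' interpolation; outside the field's grid the displacement is zero.
#' This is the representation produced by [invert_transform()].
#'
#' @param geom grid geometry the field is sampled on.
#' @param disp 4D array `(n1, n2, n3, 3)` of displacements (mm).
#' @export
displacement_transform <- function(geom, disp) {
  g <- vol_geometry(geom)
  stopifnot(length(dim(disp)) == 4L, all(dim(disp)[1:3] == g$shape),
            dim(disp)[4] == 3L)
  structure(list(geom = g, disp = disp),
            class = c("displacement_transform", "spatial_transform"))
}

#' Composite transform
#'
#' An ordered list of transforms applied innermost-first: element 1 is
#' applied to the point first (in the registration hierarchy, the affine
#' stage), then element 2 (the B-spline stage), and so on.  An empty list is
#' the identity.
#'
#' @param transforms list of `spatial_transform` objects.
#' @export
composite_transform <- function(transforms = list()) {
  if (inherits(transforms, "spatial_transform")) transforms <- list(transforms)
  ok <- vapply(transforms, inherits, TRUE, what = "spatial_transform")
  if (length(transforms) && !all(ok)) stop("all elements must be transforms")
  structure(list(transforms = transforms),
            class = c("composite_transform", "spatial_transform"))
}

#' Apply a spatial transform to physical points
#'
#' Transforms map points of the resampling target space into source space
#' (pull-back convention, as in standard registration practice).
#'
#' @param t a `spatial_transform`.
#' @param pts `n x 3` matrix of mm coordinates (a length-3 vector is accepted
#'   and treated as one point).
#' @return `n x 3` matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  UseMethod("transform_points")
}

#' @export
transform_points.affine_transform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  R <- euler_zyx_matrix(t$rotation)
  xc <- sweep(pts, 2, t$center)
  y <- t$scale * (xc %*% t(R))
  sweep(y, 2, t$center + t$translation, FUN = "+")
}

#' @export
transform_points.bspline_transform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  u <- sweep(sweep(pts, 2, t$lattice_origin), 2, t$grid_spacing, FUN = "/")
  ncp <- dim(t$coef)[1:3]
  for (d in 1:3) {
    bad <- which(u[, d] < 1 | u[, d] > ncp[d] - 2)
    if (length(bad))
      stop(sprintf(
        "point outside B-spline support on axis %d (first offender: %.3f mm)",
        d, pts[bad[1], d]))
  }
  pts + cpp_bspline_disp(t$coef, dim(t$coef)[1:3], u)
}

#' @export
transform_points.displacement_transform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  idx <- world_to_index(t$geom, pts)
  d <- vapply(1:3, function(k)
    cpp_interp_trilinear(t$disp[, , , k], t$geom$shape, idx, 0), numeric(nrow(pts)))
  pts + d
}

#' @export
transform_points.composite_transform <- function(t, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  for (tr in t$transforms) pts <- transform_points(tr, pts)
  pts
}

#' Displacement field of a transform sampled on a grid
#'
#' @param t transform.
#' @param geom geometry to sample on.
#' @return 4D array `(shape, 3)` of `T(x) - x` (mm).
#' @export
sample_displacement <- function(t, geom) {
  g <- vol_geometry(geom)
  pts <- grid_points(g)
  d <- transform_points(t, pts) - pts
  array(d, c(g$shape, 3L))
}

#' Resample a volume through a spatial transform
#'
#' Pull-back resampling: output voxel `v` receives the source intensity at
#' `T(physical(v))`.  Intensity images use trilinear interpolation
#' (`mode = "linear"`); label volumes must use `mode = "nearest"` and keep
#' their `label_map`.  Samples falling outside the source domain receive
#' `fill` (default 0, i.e. background for labels).
#'
#' @param img `image_volume` or `label_volume` to sample from.
#' @param t transform mapping reference-space points into `img` space.
#' @param ref geometry (or volume) of the output grid; defaults to the grid
#'   of `img`.
#' @param mode `"linear"` or `"nearest"`; `"nearest"` is mandatory (and the
#'   default) for label volumes.
#' @param fill value for out-of-domain samples.
#' @return Volume of the same type as `img` on the `ref` grid.
#' @export
resample <- function(img, t, ref = img,
                     mode = if (inherits(img, "label_volume")) "nearest" else "linear",
                     fill = 0) {
  mode <- match.arg(mode, c("linear", "nearest"))
  if (inherits(img, "label_volume") && mode == "linear")
    stop("linear interpolation is not defined for label volumes; use mode = \"nearest\"")
  g <- vol_geometry(ref)
  pts <- grid_points(g)
  y <- transform_points(t, pts)
  idx <- world_to_index(img, y)
  src <- img$data
  storage.mode(src) <- "double"
  vals <- if (mode == "linear")
    cpp_interp_trilinear(src, dim(img$data), idx, fill)
  else
    cpp_interp_nearest(src, dim(img$data), idx, fill)
  out <- array(vals, g$shape)
  if (inherits(img, "label_volume"))
    label_volume(out, g$spacing, g$origin,
                 label_map = img$label_map)
  else
    image_volume(out, g$spacing, g$origin)
}

#' Numerically invert a transform on a domain
#'
#' Solves `T'(T(x)) = x` by fixed-point iteration on a dense displacement
#' field sampled on `domain`: `e_{k+1}(y) = -d(y + e_k(y))` with `d` the
#' forward displacement field.  The result is returned as a
#' [displacement_transform()].  The caller is responsible for `t` being a
#' diffeomorphism on the domain; the achieved residual
#' `max || T'(T(x)) - x ||` is checked a posteriori on a subsample of the
#' domain grid and an error is raised when it exceeds `tol`.
#'
#' @param t transform to invert.
#' @param domain grid geometry on which the inverse is represented.
#' @param tol maximum admissible inversion residual (mm).
#' @param max_iter fixed-point iteration budget.
#' @param upsample integer refinement factor of the stored inverse field
#'   relative to `domain`; where the forward map has strong local strain the
#'   inverse displacement varies sharply and a finer grid reduces the
#'   trilinear representation error.
#' @return A `displacement_transform` approximating the inverse of `t`.
#' @export
invert_transform <- function(t, domain, tol = 0.1, max_iter = 50,
                             upsample = 1L) {
  g <- vol_geometry(domain)
  if (upsample > 1L)
    g <- grid_geometry((g$shape - 1L) * as.integer(upsample) + 1L,
                       g$spacing / upsample, g$origin)
  pts <- grid_points(g)
  fwd <- transform_points(t, pts) - pts        # d(x) on the domain grid
  darr <- array(fwd, c(g$shape, 3L))
  # represent the inverse on a domain padded beyond the forward range, so
  # T'(T(x)) stays inside the field for every x in the domain; the forward
  # field is edge-replicated into the pad (only consulted when the fixed
  # point strays outside the original domain)
  pad <- pmin(ceiling(max(abs(fwd)) / g$spacing) + 2L, 64L)
  gp <- grid_geometry(g$shape + 2L * pad, g$spacing, g$origin - pad * g$spacing)
  clamp <- lapply(1:3, function(d)
    pmin(pmax(seq_len(gp$shape[d]) - pad[d], 1L), g$shape[d]))
  dpad <- darr[clamp[[1]], clamp[[2]], clamp[[3]], , drop = FALSE]
  ppts <- grid_points(gp)
  e <- matrix(0, nrow(ppts), 3)
  omega <- 0.7   # under-relaxation: keeps the iteration stable where the
                 # forward field has strong local gradients
  for (k in seq_len(max_iter)) {
    idx <- world_to_index(gp, ppts + e)
    dk <- vapply(1:3, function(d)
      cpp_interp_trilinear(dpad[, , , d], gp$shape, idx, 0), numeric(nrow(ppts)))
    enew <- (1 - omega) * e - omega * dk
    delta <- max(abs(enew - e))
    e <- enew
    if (delta < 0.05 * tol) break
  }
  # polish the node values against the exact transform: solve T(x) = y per
  # node for pre-images that stay on the forward domain (where t is defined
  # and which are the only ones the residual contract concerns)
  x <- ppts + e
  lo <- g$origin - 1.5 * g$spacing
  hi <- g$origin + (g$shape + 0.5) * g$spacing
  ins <- x[, 1] >= lo[1] & x[, 1] <= hi[1] &
         x[, 2] >= lo[2] & x[, 2] <= hi[2] &
         x[, 3] >= lo[3] & x[, 3] <= hi[3]
  if (any(ins)) {
    xi <- x[ins, , drop = FALSE]
    yi <- ppts[ins, , drop = FALSE]
    lo2 <- lo - g$spacing
    hi2 <- hi + g$spacing
    for (k in seq_len(max_iter)) {
      r <- transform_points(t, xi) - yi
      if (max(abs(r)) < 0.02 * tol) break
      xi <- xi - omega * r
      for (d in 1:3) xi[, d] <- pmin(pmax(xi[, d], lo2[d]), hi2[d])
    }
    e[ins, ] <- xi - yi
  }
  inv <- displacement_transform(gp, array(e, c(gp$shape, 3L)))
  # residual check on a subsample of the original domain:
  # x -> T(x) -> T'(T(x)) vs x
  n <- nrow(pts)
  sub <- seq(1, n, by = max(1L, floor(n / 8000)))
  tx <- transform_points(t, pts[sub, , drop = FALSE])
  back <- transform_points(inv, tx)
  resid <- sqrt(rowSums((back - pts[sub, , drop = FALSE])^2))
  achieved <- max(resid)
  if (achieved > tol)
    stop(sprintf("transform inversion failed: residual %.4f mm > tol %.4f mm",
                 achieved, tol))
  attr(inv, "residual") <- achieved
  inv
}
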