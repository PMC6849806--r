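#' Dice overlap index
#'
#' `2 |A n B| / (|A| + |B|)` for two binary masks on a common grid.  When
#' both masks are empty the Dice index is defined as 1 (perfect agreement on
#' the absence of the structure).
#'
#' @param a,b logical/0-1 arrays or volumes on a common grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- as_mask(a); mb <- as_mask(b)
  if (inherits(a, "volume3d") && inherits(b, "volume3d"))
    stop_if_grid_mismatch(a, b, "masks")
  if (!all(dim(ma) == dim(mb))) stop("masks are not on a common grid")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}

as_mask <- function(x) {
  if (inherits(x, "volume3d")) x <- x$data
  x != 0
}

#' Triangulated surface of a binary mask
#'
#' The mask is converted to a signed distance field (negative inside,
#' computed from the anisotropic Euclidean distance transform of voxel
#' centres) and its zero level set -- the surface midway between inside and
#' outside voxel centres, i.e. the 0.5-isosurface of the mask -- is
#' triangulated by marching tetrahedra in physical mm coordinates.
#' Working on the signed distance field rather than the raw binary values
#' places vertices with sub-voxel accuracy, so measured areas approach the
#' continuous surface area; single-voxel masks still yield a small closed
#' mesh.
#'
#' The raw zero-crossing mesh inherits voxel-scale bumps from the discrete
#' distance field; a few passes of Taubin's non-shrinking lambda/mu smoothing
#' (default 40) remove them so measured areas track the continuous surface.
#' Set `smooth_iter = 0` for the raw piecewise-linear isosurface.
#'
#' @param mask binary array or volume (`label_volume` foreground is any
#'   nonzero voxel unless `label` is given).
#' @param spacing,origin grid geometry when `mask` is a bare array.
#' @param label optional label value(s) to select from a `label_volume`.
#' @param smooth_iter Taubin smoothing passes applied to the mesh.
#' @return A `surface_mesh`: list with `vertices` (`V x 3` mm) and `faces`
#'   (`F x 3`, 1-based indices).
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            label = NULL, smooth_iter = 40) {
  if (inherits(mask, "volume3d")) {
    g <- vol_geometry(mask)
    spacing <- g$spacing; origin <- g$origin
    m <- if (is.null(label)) mask$data != 0 else mask$data %in% label
    dim(m) <- g$shape
  } else m <- mask != 0
  if (!any(m)) stop("cannot extract a surface from an empty mask")
  phi <- signed_distance(m, spacing)
  # pad so surfaces at the volume border close
  pd <- dim(phi) + 2L
  pp <- array(max(spacing) * 2, pd)
  pp[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- phi
  mesh <- cpp_marching_tetrahedra(pp, pd, 0, spacing, origin - spacing)
  if (nrow(mesh$faces) == 0) stop("degenerate mask produced no surface")
  mesh <- structure(list(vertices = mesh$vertices, faces = mesh$faces),
                    class = "surface_mesh")
  # tiny closed meshes (a handful of vertices) collapse under smoothing;
  # leave them as the raw isosurface
  if (smooth_iter > 0 && nrow(mesh$vertices) >= 100)
    mesh <- taubin_smooth(mesh, smooth_iter)
  mesh
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternating Laplacian steps with positive (`lambda`) and negative (`mu`)
#' weights; unlike plain Laplacian smoothing the pair does not shrink closed
#' surfaces.
#'
#' @param mesh a `surface_mesh`.
#' @param iters smoothing passes.
#' @param lambda,mu step weights (`0 < lambda < -mu`).
#' @export
taubin_smooth <- function(mesh, iters = 40, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ed <- unique(rbind(ed, ed[, 2:1]))
  ed <- ed[order(ed[, 1]), , drop = FALSE]
  deg <- tabulate(ed[, 1], nv)
  deg[deg == 0] <- 1
  for (it in seq_len(iters)) {
    for (fac in c(lambda, mu)) {
      nb <- rowsum(v[ed[, 2], , drop = FALSE], ed[, 1], reorder = TRUE)
      v <- v + fac * (nb / deg - v)
    }
  }
  mesh$vertices <- v
  mesh
}

# signed distance (mm): negative inside, positive outside.  The raw
# centre-to-centre distances overshoot the interface (which lies midway
# between opposite-class centres) by half a voxel on each side; subtracting
# that offset makes the field interface-accurate for flat boundaries.
signed_distance <- function(mask, spacing) {
  d_in <- cpp_edt_sq(!mask, dim(mask), spacing)   # distance to outside
  d_out <- cpp_edt_sq(mask, dim(mask), spacing)   # distance to inside
  phi <- sqrt(d_out) - sqrt(d_in)
  phi[is.infinite(phi) & phi > 0] <- max(dim(mask) * spacing)
  phi[is.infinite(phi) & phi < 0] <- -max(dim(mask) * spacing)
  phi <- phi - 0.5 * mean(spacing) * sign(phi)
  dim(phi) <- dim(mask)
  phi
}

#' Total area of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, area", signif(mesh_area(x), 5), "mm^2\n")
  invisible(x)
}

#' Directed surface-to-surface distance
#'
#' Mean, over the vertices of the automatically segmented surface, of the
#' exact point-to-triangle distance to the ground-truth surface.  The
#' measure is directed (auto to GT) following its standard definition;
#' `symmetric = TRUE` averages both directions instead.
#'
#' @param auto automatic `surface_mesh`.
#' @param gt ground-truth `surface_mesh`.
#' @param symmetric average the two directed distances.
#' @return Mean distance in mm.
#' @export
s2s_distance <- function(auto, gt, symmetric = FALSE) {
  check_mesh(auto); check_mesh(gt)
  d <- mean(cpp_point_mesh_dist(auto$vertices, gt$vertices, gt$faces))
  if (symmetric)
    d <- (d + mean(cpp_point_mesh_dist(gt$vertices, auto$vertices, auto$faces))) / 2
  d
}

check_mesh <- function(m) {
  if (!is.list(m) || is.null(m$vertices) || is.null(m$faces) ||
      nrow(m$vertices) == 0 || nrow(m$faces) == 0)
    stop("empty or malformed surface mesh")
  if (max(m$faces) > nrow(m$vertices) || min(m$faces) < 1)
    stop("mesh face indices out of range")
  invisible(TRUE)
}

#' Per-structure segmentation accuracy report
#'
#' Dice and mean directed surface-to-surface distance for the whole left
#' atrium (union of all foreground labels) and for each anatomical
#' component.  Structures empty in both segmentation and ground truth get
#' Dice 1 and an `NA` S2S with `skipped = TRUE`.
#'
#' @param seg automatic `label_volume`.
#' @param gt ground-truth `label_volume` on the same grid with the same
#'   `label_map`.
#' @return Data frame with one row per structure (plus `whole_LA`):
#'   `structure`, `label`, `dice`, `s2s_mm`, `n_seg`, `n_gt`, `skipped`.
#' @export
evaluate <- function(seg, gt) {
  stopifnot(inherits(seg, "label_volume"), inherits(gt, "label_volume"))
  stop_if_grid_mismatch(seg, gt, "segmentation and ground truth")
  if (!identical(seg$label_map, gt$label_map))
    stop("segmentation and ground truth use different label maps")
  lm <- seg$label_map
  fg <- setdiff(as.integer(lm), 0L)
  rows <- list()
  eval_one <- function(name, labels) {
    ms <- seg$data %in% labels; dim(ms) <- dim(seg$data)
    mg <- gt$data %in% labels; dim(mg) <- dim(gt$data)
    d <- dice(ms, mg)
    skipped <- !any(ms) || !any(mg)
    s2s <- NA_real_
    if (!skipped) {
      sa <- extract_surface(ms, seg$spacing, seg$origin)
      sg <- extract_surface(mg, gt$spacing, gt$origin)
      s2s <- s2s_distance(sa, sg)
    }
    data.frame(structure = name,
               label = if (length(labels) == 1) labels else NA_integer_,
               dice = d, s2s_mm = s2s,
               n_seg = sum(ms), n_gt = sum(mg), skipped = skipped,
               stringsAsFactors = FALSE)
  }
  rows[["whole_LA"]] <- eval_one("whole_LA", fg)
  for (nm in names(lm)[lm != 0])
    rows[[nm]] <- eval_one(nm, lm[[nm]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a mesh as ASCII PLY or STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output file; format chosen from the extension (`.ply`/`.stl`).
#' @export
write_mesh <- function(mesh, path) {
  check_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- c(0, 0, 0)
      writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
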