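#' 3D scalar image with physical grid geometry
#'
#' An `image_volume` holds a 3D numeric array together with its voxel spacing
#' (mm/voxel) and origin (mm).  The physical coordinate of the voxel with
#' 0-based index `v` (R arrays are 1-based, so array element `[i, j, k]` has
#' 0-based index `(i-1, j-1, k-1)`) is `origin + v * spacing`, axis by axis.
#' This index-to-world convention is used consistently by every transform and
#' resampling routine in the package.
#'
#' @param data 3D numeric array (each axis length >= 1).
#' @param spacing numeric length-3, voxel size in mm along each array axis;
#'   all components must be positive.
#' @param origin numeric length-3, physical position (mm) of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(1.25, 1.25, 2.27))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = c("image_volume", "volume3d"))
}

#' 3D integer label map sharing a grid with an image
#'
#' A `label_volume` is the annotation counterpart of [image_volume()]: an
#' integer array on the same physical grid, whose values are keys of
#' `label_map`.  The default roster covers the left-atrial anatomy carried
#' end-to-end by the pipeline: background, LA chamber, the four pulmonary
#' veins (LSPV, LIPV, RSPV, RIPV) and the left atrial appendage (LAA).
#'
#' @param data 3D integer array.
#' @param spacing,origin grid geometry, as for [image_volume()].
#' @param label_map named integer vector mapping structure names to label
#'   values; every voxel value must be one of these values.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         label_map = la_label_map()) {
  data <- as_array3(data)
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("all spacing components must be positive")
  bad <- setdiff(unique(as.vector(data)), as.integer(label_map))
  if (length(bad))
    stop("voxel values not present in label_map: ", paste(bad, collapse = ", "))
  structure(list(data = data, spacing = spacing, origin = origin,
                 label_map = label_map),
            class = c("label_volume", "volume3d"))
}

#' Canonical left-atrium label roster
#'
#' @return Named integer vector: background (0), LA chamber (1), left/right
#'   superior/inferior pulmonary veins (2-5), left atrial appendage (6).
#' @export
la_label_map <- function() {
  c(background = 0L, LA_chamber = 1L, LSPV = 2L, LIPV = 3L,
    RSPV = 4L, RIPV = 5L, LAA = 6L)
}

#' Tube (pulmonary vein) label values
#' @return Integer vector of the four PV labels (2-5).
#' @export
pv_labels <- function() c(2L, 3L, 4L, 5L)

as_array3 <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("data must have three axes")
  if (any(dim(x) < 1L)) stop("each axis must have length >= 1")
  x
}

#' Grid geometry of a volume
#'
#' @param x an `image_volume`/`label_volume`, or a geometry list.
#' @return List with `shape`, `spacing`, `origin`.
#' @export
vol_geometry <- function(x) {
  if (inherits(x, "volume3d"))
    return(list(shape = dim(x$data), spacing = x$spacing, origin = x$origin))
  if (is.list(x) && all(c("shape", "spacing", "origin") %in% names(x)))
    return(x[c("shape", "spacing", "origin")])
  stop("cannot interpret grid geometry")
}

#' Construct a grid geometry
#' @param shape integer length-3 array dimensions.
#' @param spacing,origin as for [image_volume()].
#' @export
grid_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  list(shape = as.integer(shape), spacing = as.numeric(spacing),
       origin = as.numeric(origin))
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume", paste(dim(x$data), collapse = " x "),
      " spacing [mm]:", paste(signif(x$spacing, 4), collapse = ", "),
      " origin:", paste(signif(x$origin, 4), collapse = ", "),
      " range:", paste(signif(range(x$data), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$data, levels = x$label_map,
                      labels = names(x$label_map)))
  cat("label_volume", paste(dim(x$data), collapse = " x "),
      " spacing [mm]:", paste(signif(x$spacing, 4), collapse = ", "), "\n")
  print(tab)
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- vol_geometry(a); gb <- vol_geometry(b)
  all(ga$shape == gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " are not on a common grid")
  invisible(TRUE)
}

#' Physical coordinates of every voxel centre
#'
#' @param geom geometry (or volume).
#' @return `prod(shape) x 3` matrix of mm coordinates, voxels in array
#'   (column-major) order.
#' @export
grid_points <- function(geom) {
  g <- vol_geometry(geom)
  ax <- lapply(1:3, function(d) g$origin[d] + (seq_len(g$shape[d]) - 1) * g$spacing[d])
  n1 <- g$shape[1]; n2 <- g$shape[2]; n3 <- g$shape[3]
  cbind(rep(ax[[1]], times = n2 * n3),
        rep(rep(ax[[2]], each = n1), times = n3),
        rep(ax[[3]], each = n1 * n2))
}

# world (mm) -> continuous 0-based voxel index of a grid
world_to_index <- function(geom, pts) {
  g <- vol_geometry(geom)
  cbind((pts[, 1] - g$origin[1]) / g$spacing[1],
        (pts[, 2] - g$origin[2]) / g$spacing[2],
        (pts[, 3] - g$origin[3]) / g$spacing[3])
}

index_to_world <- function(geom, idx) {
  g <- vol_geometry(geom)
  cbind(g$origin[1] + idx[, 1] * g$spacing[1],
        g$origin[2] + idx[, 2] * g$spacing[2],
        g$origin[3] + idx[, 3] * g$spacing[3])
}
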