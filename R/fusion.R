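#' Propagate atlas labels to the mean-shape grid
#'
#' Resamples each atlas label volume onto the common (mean-shape) reference
#' grid through its groupwise transform, with nearest-neighbour
#' interpolation.  Ensemble element 1 belongs to the target and is not used
#' here; elements `2..N+1` must correspond to `labels` in order.
#'
#' @param labels list of `N` `label_volume`s, one per atlas.
#' @param ensemble a [group_transform_ensemble()] from [register_joint()].
#' @return List of `N` `label_volume`s on the reference grid.
#' @export
propagate_labels <- function(labels, ensemble) {
  stopifnot(inherits(ensemble, "group_transform_ensemble"))
  if (length(labels) != length(ensemble$transforms) - 1)
    stop("label count does not match the ensemble's atlas count")
  lapply(seq_along(labels), function(i)
    resample(labels[[i]], ensemble$transforms[[i + 1]],
             ref = ensemble$ref_geom, mode = "nearest", fill = 0))
}

#' Majority-vote label fusion
#'
#' Per voxel, the label value with the highest count among the propagated
#' label volumes; ties are broken toward the smaller label value, so
#' background wins a background/structure tie (conservative rule).  Fusion
#' is joint over all label values, preserving the identity of each
#' pulmonary vein and the appendage.  The same fusion is used in both the
#' joint pipeline (on the mean-shape grid) and the pairwise baseline (on the
#' target grid).
#'
#' @param propagated nonempty list of `label_volume`s on a common grid.
#' @return Fused `label_volume`.
#' @export
majority_vote <- function(propagated) {
  if (!length(propagated)) stop("majority_vote needs at least one label volume")
  for (p in propagated[-1])
    stop_if_grid_mismatch(propagated[[1]], p, "propagated labels")
  lm <- propagated[[1]]$label_map
  values <- sort(unique(unlist(lapply(propagated, function(p)
    unique(as.vector(p$data))))))
  nvox <- length(propagated[[1]]$data)
  best <- rep(values[1], nvox)
  best_n <- integer(nvox)
  for (v in values) {                      # ascending: ties keep smaller label
    cnt <- integer(nvox)
    for (p in propagated) cnt <- cnt + (as.vector(p$data) == v)
    take <- cnt > best_n
    best[take] <- v
    best_n[take] <- cnt[take]
  }
  label_volume(array(best, dim(propagated[[1]]$data)),
               propagated[[1]]$spacing, propagated[[1]]$origin, label_map = lm)
}

#' Back-propagate a mean-shape segmentation to the target image
#'
#' Inverts the target's groupwise transform (ensemble element 1) on the
#' target grid and pulls the fused segmentation through it with
#' nearest-neighbour interpolation.
#'
#' @param seg fused `label_volume` on the mean-shape grid.
#' @param ensemble a [group_transform_ensemble()].
#' @param target_geom geometry (or volume) of the target grid.
#' @param tol maximum inversion residual; the default is half the smallest
#'   voxel spacing -- the accuracy scale at which nearest-neighbour label
#'   pull-back is quantized anyway.
#' @param max_iter forwarded to [invert_transform()].
#' @return `label_volume` on the target grid.
#' @export
backpropagate <- function(seg, ensemble, target_geom, tol = NULL,
                          max_iter = 100) {
  stopifnot(inherits(ensemble, "group_transform_ensemble"),
            inherits(seg, "label_volume"))
  g <- vol_geometry(target_geom)
  if (is.null(tol)) tol <- 0.5 * min(g$spacing)
  inv <- invert_transform(ensemble$transforms[[1]], target_geom,
                          tol = tol, max_iter = max_iter, upsample = 2L)
  resample(seg, inv, ref = target_geom, mode = "nearest", fill = 0)
}
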