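make_ensemble <- function(transforms, ref) {
  group_transform_ensemble(transforms, ref)
}

test_that("label propagation follows the atlas transforms", {
  lab <- label_volume(array(c(rep(0L, 20), rep(1L, 24), rep(0L, 20)),
                            c(4, 4, 4)), c(2, 2, 2))
  ref <- grid_geometry(c(4, 4, 4), c(2, 2, 2))
  ens <- make_ensemble(list(composite_transform(),     # target
                            composite_transform(),
                            composite_transform()), ref)
  pr <- propagate_labels(list(lab, lab), ens)
  expect_equal(pr[[1]]$data, lab$data)
  # translation by exactly one voxel shifts the labels one voxel
  sh <- affine_transform(translation = c(2, 0, 0))
  ens2 <- make_ensemble(list(composite_transform(), sh, composite_transform()),
                        ref)
  pr2 <- propagate_labels(list(lab, lab), ens2)
  expect_equal(pr2[[1]]$data[1:3, , ], lab$data[2:4, , ])
  expect_equal(pr2[[2]]$data, lab$data)
  expect_error(propagate_labels(list(lab), ens), "count")
})

test_that("propagation through a known warp tracks the analytic geometry", {
  g <- grid_geometry(c(32, 32, 32), c(2, 2, 2))
  cidx <- c(16.5, 16.5, 16.5)                 # sphere centre, index units
  pc <- (cidx - 1) * 2                        # physical centre (mm)
  sph <- sphere_mask(c(32, 32, 32), center = cidx, radius = 18,
                     spacing = c(2, 2, 2))
  lab <- label_volume(array(as.integer(sph), dim(sph)), c(2, 2, 2))
  set.seed(6)
  w <- bspline_lattice(g, 24)
  w$coef <- array(runif(length(w$coef), -4, 4), dim(w$coef))
  ens <- make_ensemble(list(composite_transform(), w), g)
  pr <- propagate_labels(list(lab), ens)[[1]]
  # analytic truth: voxel v is foreground iff its warped position lies in
  # the sphere
  pts <- transform_points(w, grid_points(g))
  truth <- rowSums(sweep(pts, 2, pc)^2) <= 18^2
  expect_gt(dice(array(pr$data == 1L, dim(sph)), array(truth, dim(sph))), 0.95)
})

test_that("majority voting takes the modal label with background-first ties", {
  mk <- function(v) label_volume(array(as.integer(v), c(length(v), 1, 1)))
  # unanimous
  expect_equal(majority_vote(list(mk(c(1, 2)), mk(c(1, 2))))$data[, 1, 1],
               c(1L, 2L))
  # strict majority {1, 1, 2} -> 1
  expect_equal(majority_vote(list(mk(1), mk(1), mk(2)))$data[1, 1, 1], 1L)
  # N = 2 tie {1, 2} -> smaller label wins
  expect_equal(majority_vote(list(mk(1), mk(2)))$data[1, 1, 1], 1L)
  expect_equal(majority_vote(list(mk(0), mk(6)))$data[1, 1, 1], 0L)
  expect_error(majority_vote(list()), "at least one")
})

test_that("majority voting is permutation invariant and label-closed", {
  set.seed(12)
  vols <- lapply(1:5, function(i)
    label_volume(array(sample(c(0L, 1L, 3L, 6L), 64, TRUE), c(4, 4, 4))))
  f1 <- majority_vote(vols)
  f2 <- majority_vote(vols[c(4, 2, 5, 1, 3)])
  expect_identical(f1$data, f2$data)
  expect_true(all(f1$data %in% c(0L, 1L, 3L, 6L)))
})

test_that("back-propagation inverts the target transform", {
  lab <- label_volume(array(c(rep(0L, 24), rep(2L, 16), rep(0L, 24)),
                            c(4, 4, 4)), c(2, 2, 2))
  ref <- grid_geometry(c(4, 4, 4), c(2, 2, 2))
  ens0 <- make_ensemble(list(composite_transform(), composite_transform(),
                             composite_transform()), ref)
  expect_equal(backpropagate(lab, ens0, ref)$data, lab$data)
  # pure translation: segmentation shifts by the inverse translation
  sh <- affine_transform(translation = c(2, 0, 0))
  ens1 <- make_ensemble(list(sh, composite_transform(), composite_transform()),
                        ref)
  bp <- backpropagate(lab, ens1, ref)
  expect_equal(bp$data[2:4, , ], lab$data[1:3, , ])
})

test_that("smooth warp round-trip through the mean-shape grid preserves the mask", {
  g <- grid_geometry(c(32, 32, 32), c(2, 2, 2))
  sph <- sphere_mask(c(32, 32, 32), center = c(16, 16, 16), radius = 20,
                     spacing = c(2, 2, 2))
  lab <- label_volume(array(as.integer(sph), dim(sph)), c(2, 2, 2))
  set.seed(7)
  w <- bspline_lattice(g, 24)
  w$coef <- array(runif(length(w$coef), -4, 4), dim(w$coef))
  ens <- make_ensemble(list(w, composite_transform()), g)
  # pull the target mask onto the mean-shape grid through the target's
  # forward transform (as the fused segmentation lives there)...
  on_mean <- resample(lab, w, ref = g, mode = "nearest", fill = 0)
  # ...then the pipeline's back-propagation must restore it
  back <- backpropagate(on_mean, ens, g)
  expect_gt(dice(array(back$data != 0, dim(sph)), sph), 0.98)
})
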