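test_that("region means are the smoothed-Heaviside weighted averages", {
  # binary object with exact signed distance: means within 1 intensity
  # unit.  The smoothed transition band trades mass across the interface,
  # so the accuracy statement concerns objects whose surface-to-volume
  # ratio is small against the band width (here a half-split slab).
  slab <- array(FALSE, c(48, 8, 8)); slab[1:24, , ] <- TRUE
  img <- image_volume(array(ifelse(slab, 100, 0), dim(slab)))
  phi <- jointatlas:::signed_distance(slab, c(1, 1, 1))
  cm <- region_means(img, phi, epsilon = 1)
  expect_lt(abs(cm[["c1"]] - 100), 1)
  expect_lt(abs(cm[["c2"]] - 0), 1)
  # constant image: both means equal the constant
  img7 <- image_volume(array(7, c(8, 8, 8)))
  phi7 <- jointatlas:::signed_distance(sphere_mask(c(8, 8, 8), c(4, 4, 4), 2),
                                       c(1, 1, 1))
  expect_equal(unname(region_means(img7, phi7)), c(7, 7))
  # 1D toy profile: means equal directly computed weighted averages
  vals <- c(10, 20, 30, 40, 50, 60)
  img1 <- image_volume(array(vals, c(6, 1, 1)))
  phi1 <- array(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), c(6, 1, 1))
  eps <- 1
  h_in <- jointatlas:::heaviside_eps(-phi1, eps)
  want <- c(sum(vals * h_in) / sum(h_in),
            sum(vals * (1 - h_in)) / sum(1 - h_in))
  expect_equal(unname(region_means(img1, phi1, eps)), want)
  # one-sided configurations are rejected
  expect_error(region_means(img7, array(-5, c(8, 8, 8))), "vanishing")
})

test_that("the energy vanishes for a perfect two-constant fit and counts area", {
  box <- array(FALSE, c(16, 16, 16)); box[5:12, 5:12, 5:12] <- TRUE
  img <- image_volume(array(ifelse(box, 150, 20), dim(box)))
  phi <- jointatlas:::signed_distance(box, c(1, 1, 1))
  p0 <- level_set_params(mu = 0, nu = 0)
  expect_lt(chan_vese_energy(img, phi, p0), 1e-6 * sum(img$data^2))
  # area term: an 8-voxel cube has 6 * 8^2 face area; co-area estimate close
  p1 <- level_set_params(mu = 1, nu = 0)
  e1 <- chan_vese_energy(img, phi, p1)
  expect_lt(abs(e1 - 6 * 64) / (6 * 64), 0.25)
  # volume term counts the inside
  p2 <- level_set_params(mu = 0, nu = 1)
  expect_lt(abs(chan_vese_energy(img, phi, p2) - sum(box)) / sum(box), 0.05)
})

test_that("misplacing the boundary strictly increases the data energy", {
  box <- array(FALSE, c(16, 16, 16)); box[5:12, 5:12, 5:12] <- TRUE
  img <- image_volume(array(ifelse(box, 150, 20), dim(box)))
  p0 <- level_set_params(mu = 0, nu = 0)
  e_right <- chan_vese_energy(img, jointatlas:::signed_distance(box, c(1, 1, 1)), p0)
  shifted <- array(FALSE, dim(box)); shifted[8:15, 5:12, 5:12] <- TRUE
  e_wrong <- chan_vese_energy(img, jointatlas:::signed_distance(shifted, c(1, 1, 1)), p0)
  expect_gt(e_wrong, e_right)
})

test_that("evolution converges to the object and is deterministic", {
  sph <- sphere_mask(c(32, 32, 32), c(16, 16, 16), 10)
  img <- image_volume(array(ifelse(sph, 200, 30), dim(sph)))
  init <- dilate_mask(sph, 2)
  p <- level_set_params(n_iter = 150)
  seg <- level_set_evolve(img, init, p)
  expect_gt(dice(seg, sph), 0.98)
  # already optimal: stationary
  seg0 <- level_set_evolve(img, sph, p)
  expect_gt(dice(seg0, sph), 0.99)
  # no randomness: identical reruns
  seg2 <- level_set_evolve(img, init, p)
  expect_identical(seg$data, seg2$data)
  expect_error(level_set_evolve(img, array(FALSE, dim(sph))), "empty")
})

test_that("the data terms are covariant under affine intensity rescaling", {
  sph <- sphere_mask(c(24, 24, 24), c(12, 12, 12), 8)
  img <- image_volume(array(ifelse(sph, 180, 40), dim(sph)))
  init <- dilate_mask(sph, 1)
  p <- level_set_params(mu = 0, nu = 0, n_iter = 80)
  s1 <- level_set_evolve(img, init, p)
  img2 <- image_volume(img$data * 3 + 11, img$spacing, img$origin)
  s2 <- level_set_evolve(img2, init, p)
  expect_identical(s1$data, s2$data)
})

test_that("refinement preserves the label partition and recovers missing structure", {
  spec <- tiny_phantom_spec(seed = 4, noise_sigma = 0, bias_amplitude = 0)
  tpl <- make_template(spec)
  gt <- tpl$labels
  # clip the distal half of one PV tube from the initialization
  fused <- gt
  idx <- which(fused$data == 2L, arr.ind = TRUE)
  cut <- idx[, 1] > quantile(idx[, 1], 0.5)
  fused$data[idx[cut, , drop = FALSE]] <- 0L
  missing_vox <- which(gt$data == 2L & fused$data == 0L)
  p <- level_set_params(n_iter = 150)
  ref <- refine_segmentation(tpl$image, fused, p)
  # at least half of the clipped tube voxels are recovered
  expect_gt(mean(ref$data[missing_vox] != 0L), 0.5)
  # refined foreground voxel count equals the sum of per-label counts
  tab <- table(ref$data[ref$data != 0])
  expect_equal(sum(ref$data != 0L), sum(tab))
  expect_true(all(ref$data %in% gt$label_map))
  # an already-optimal fusion stays put up to convergence tolerance
  ref0 <- refine_segmentation(tpl$image, gt, p)
  expect_gt(dice(array(ref0$data != 0, dim(gt$data)),
                 array(gt$data != 0, dim(gt$data))), 0.99)
})

test_that("the smoothed energy trace is non-increasing during evolution", {
  sph <- sphere_mask(c(32, 32, 32), c(16, 16, 16), 10)
  img <- image_volume(array(ifelse(sph, 200, 30), dim(sph)))
  seg <- level_set_evolve(img, dilate_mask(sph, 2), level_set_params(n_iter = 120))
  tr <- attr(seg, "trace")
  sm <- rolling_mean(tr, 10)
  drop_total <- sm[1] - sm[length(sm)]
  expect_gt(drop_total, 0)
  expect_lt(max(diff(sm)), 0.02 * drop_total)
})
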