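test_that("intensity normalization maps ranges linearly and handles constants", {
  img <- image_volume(array(c(0, 50, 100, 0, 50, 100, 0, 100), c(2, 2, 2)))
  n <- normalize_intensity(img, c(0, 255))
  expect_equal(sort(unique(as.vector(n$data))), c(0, 127.5, 255))
  # an image already spanning the range is unchanged
  img2 <- image_volume(array(c(0, 255, 100, 30, 0, 255, 12, 200), c(2, 2, 2)))
  expect_equal(normalize_intensity(img2, c(0, 255))$data, img2$data)
  # constant image maps to the lower bound
  img3 <- image_volume(array(42, c(2, 2, 2)))
  expect_true(all(normalize_intensity(img3, c(0, 255))$data == 0))
})

test_that("mutual information matches closed-form cases", {
  set.seed(8)
  a <- image_volume(array(runif(4096, 0, 255), c(16, 16, 16)))
  # MI(X, X) equals the marginal entropy H(X)
  bins <- 32
  ia <- jointatlas:::hist_bin(a$data, bins)
  p <- tabulate(ia, bins) / length(ia)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(a, a, bins), h, tolerance = 1e-12)
  # symmetric in its arguments
  b <- image_volume(array(runif(4096, 0, 255), c(16, 16, 16)))
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  # two-voxel anticorrelated pair with 2 bins carries exactly 1 bit
  x <- image_volume(array(c(0, 255), c(2, 1, 1)))
  y <- image_volume(array(c(255, 0), c(2, 1, 1)))
  expect_equal(mutual_information(x, y, bins = 2), 1)
  # independent noise at 64^3: MI tends to zero
  set.seed(21)
  u <- image_volume(array(runif(64^3, 0, 255), c(64, 64, 64)))
  v <- image_volume(array(runif(64^3, 0, 255), c(64, 64, 64)))
  expect_lt(mutual_information(u, v, 32), 0.05)
})

test_that("group variance and mean shape match hand-computed values", {
  one <- function(x) image_volume(array(x, c(1, 1, 1)))
  # two one-voxel images {0, 2}: mean 1, squared deviations (1 + 1) = 2
  expect_equal(group_variance(list(one(0), one(2))), 2)
  expect_equal(mean_shape(list(one(0), one(2)))$data[1], 1)
  # three images {0, 3, 6}: mean 3
  expect_equal(mean_shape(list(one(0), one(3), one(6)))$data[1], 3)
  expect_equal(group_variance(list(one(0), one(3), one(6))), 9 + 0 + 9)
  # identical images: zero variance, mean is the image
  set.seed(3)
  img <- image_volume(array(rnorm(27), c(3, 3, 3)))
  expect_equal(group_variance(list(img, img, img)), 0)
  expect_equal(mean_shape(list(img, img, img))$data, img$data)
  # adding a constant to every member leaves the variance unchanged
  shift <- function(v, k) image_volume(v$data + k, v$spacing, v$origin)
  g1 <- list(img, shift(img, 2), shift(img, -1))
  g2 <- lapply(g1, shift, k = 7)
  expect_equal(group_variance(g1), group_variance(g2))
  # permutation invariance
  expect_equal(group_variance(g1), group_variance(g1[c(3, 1, 2)]))
  expect_equal(mean_shape(g1)$data, mean_shape(g1[c(2, 3, 1)])$data)
  expect_error(group_variance(list()), "empty")
  expect_error(mean_shape(list()), "empty")
})

test_that("both registration modes consume one shared configuration schema", {
  cfg <- registration_config(n_resolutions = 2, iterations_per_resolution = 5,
                             samples_per_iteration = 64, seed = 3)
  expect_s3_class(cfg, "registration_config")
  expect_named(cfg, c("n_resolutions", "iterations_per_resolution",
                      "grid_spacing_mm", "samples_per_iteration",
                      "step_size_schedule", "seed", "intensity_range",
                      "mi_bins"))
  # defaults mirror the reference protocol: 10 mm grid, 0-255 range
  def <- registration_config()
  expect_equal(def$grid_spacing_mm, 10)
  expect_equal(def$intensity_range, c(0, 255))
  expect_equal(def$n_resolutions, 3L)
  # the same object drives both modes
  set.seed(1)
  img <- image_volume(array(runif(16^3, 0, 255), c(16, 16, 16)), c(4, 4, 4))
  expect_error(register_pairwise(img, img, cfg), NA)
  expect_error(register_joint(img, list(img, img), cfg), NA)
  expect_error(register_joint(img, list(img), cfg), "at least 2")
})

test_that("registration is deterministic and near-identity on self-registration", {
  spec <- tiny_phantom_spec(seed = 2)
  tpl <- make_template(spec)
  cfg <- registration_config(n_resolutions = 2, iterations_per_resolution = 150,
                             samples_per_iteration = 1024, seed = 10)
  t1 <- register_pairwise(tpl$image, tpl$image, cfg)
  t2 <- register_pairwise(tpl$image, tpl$image, cfg)
  expect_identical(t1$transforms[[1]]$translation, t2$transforms[[1]]$translation)
  expect_identical(t1$transforms[[2]]$coef, t2$transforms[[2]]$coef)
  # self-registration stays within 0.2 voxel mean displacement of identity
  pts <- grid_points(tpl$image)
  keep <- as.vector(tpl$labels$data != 0)
  d <- transform_points(t1, pts[keep, ]) - pts[keep, ]
  expect_lt(mean(sqrt(rowSums(d^2))), 0.2 * min(tpl$image$spacing))
})
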