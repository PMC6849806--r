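test_that("affine transforms map points per the closed form", {
  # identity
  t0 <- affine_transform()
  expect_equal(drop(transform_points(t0, c(10, 20, 30))), c(10, 20, 30))
  # pure translation
  tt <- affine_transform(translation = c(1, 2, 3))
  expect_equal(drop(transform_points(tt, c(0, 0, 0))), c(1, 2, 3))
  # isotropic scale about the origin
  ts <- affine_transform(scale = 2)
  expect_equal(drop(transform_points(ts, c(1, 1, 1))), c(2, 2, 2))
  # scale acts about the center
  tc <- affine_transform(scale = 2, center = c(1, 1, 1))
  expect_equal(drop(transform_points(tc, c(1, 1, 1))), c(1, 1, 1))
  # 90 degree rotation about z maps +x to +y
  tr <- affine_transform(rotation = c(0, 0, pi / 2))
  expect_equal(drop(transform_points(tr, c(1, 0, 0))), c(0, 1, 0))
  # ZYX composition: R = Rz Ry Rx (x-rotation applied first)
  ta <- affine_transform(rotation = c(pi / 2, 0, pi / 2))
  expect_equal(drop(transform_points(ta, c(0, 1, 0))),
               drop(transform_points(
                 affine_transform(rotation = c(0, 0, pi / 2)),
                 drop(transform_points(
                   affine_transform(rotation = c(pi / 2, 0, 0)),
                   c(0, 1, 0))))))
  expect_error(affine_transform(scale = 0), "scale")
})

test_that("B-spline displacement matches brute-force summation over all control points", {
  set.seed(4)
  bt <- bspline_transform(c(8, 10, 12), c(-16, -20, -24), ncp = c(7, 6, 8))
  bt$coef <- array(rnorm(length(bt$coef)), dim(bt$coef))
  pts <- cbind(runif(12, 0, 20), runif(12, 0, 15), runif(12, 0, 30))
  got <- transform_points(bt, pts) - pts
  want <- t(apply(pts, 1, function(x) bspline_disp_brute(bt, x)))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)
  # value at a control point with a single nonzero coefficient
  bt$coef[] <- 0
  bt$coef[4, 3, 5, ] <- c(2, -1, 3)
  xk <- bt$lattice_origin + c(3, 2, 4) * bt$grid_spacing
  expect_equal(drop(transform_points(bt, xk)) - xk,
               bspline_disp_brute(bt, xk))
})

test_that("B-spline partition of unity: uniform coefficients act as translation", {
  bt <- bspline_transform(10, c(-20, -20, -20), ncp = c(8, 8, 8))
  bt$coef[, , , 1] <- 5
  bt$coef[, , , 2] <- -2
  bt$coef[, , , 3] <- 0.5
  set.seed(1)
  pts <- matrix(runif(60, 0, 30), 20, 3)
  d <- transform_points(bt, pts) - pts
  expect_lt(max(abs(sweep(d, 2, c(5, -2, 0.5)))) / 5, 1e-9)
  # zero coefficients: identity
  bt$coef[] <- 0
  expect_equal(transform_points(bt, pts), pts)
})

test_that("B-spline support is local and violations are reported", {
  bt <- bspline_transform(10, c(-20, -20, -20), ncp = c(8, 8, 8))
  set.seed(2)
  pts <- matrix(runif(90, 0, 30), 30, 3)
  base <- transform_points(bt, pts)
  bt2 <- bt
  bt2$coef[5, 5, 5, ] <- c(3, 3, 3)     # control point at (20, 20, 20)
  moved <- transform_points(bt2, pts)
  xk <- bt$lattice_origin + c(4, 4, 4) * bt$grid_spacing
  outside <- apply(abs(sweep(pts, 2, xk)), 1, max) >= 2 * 10
  expect_true(all(moved[outside, ] == base[outside, ]))
  expect_true(any(moved[!outside, ] != base[!outside, ]))
  expect_error(transform_points(bt, matrix(c(500, 0, 0), 1)), "axis 1")
})

test_that("resample performs exact lattice-aligned and half-voxel interpolation", {
  img <- image_volume(array(seq_len(4 * 4 * 4), c(4, 4, 4)), c(2, 1, 1))
  # identity copy
  r0 <- resample(img, affine_transform())
  expect_equal(r0$data, img$data)
  # one-voxel shift along axis 1 (spacing 2mm): interior columns shift
  r1 <- resample(img, affine_transform(translation = c(2, 0, 0)), fill = NA)
  expect_equal(r1$data[1:3, , ], img$data[2:4, , ])
  # half-voxel shift on a two-valued profile
  prof <- image_volume(array(c(0, 10), c(2, 1, 1)))
  rh <- resample(prof, affine_transform(translation = c(0.5, 0, 0)), fill = NA)
  expect_equal(rh$data[1, 1, 1], 5)
  # labels require nearest-neighbour interpolation
  lab <- label_volume(array(0L, c(2, 2, 2)))
  expect_error(resample(lab, affine_transform(), mode = "linear"), "nearest")
  # label output only contains input labels plus fill
  lab2 <- label_volume(array(c(0L, 3L), c(2, 2, 2)))
  rl <- resample(lab2, affine_transform(translation = c(0.4, 0, 0)))
  expect_true(all(rl$data %in% c(0L, 3L)))
})

test_that("composite transforms apply members innermost-first and empty list is identity", {
  a <- affine_transform(translation = c(1, 0, 0))
  b <- affine_transform(scale = 2)
  comp <- composite_transform(list(a, b))
  p <- matrix(c(3, 4, 5), 1)
  expect_equal(transform_points(comp, p),
               transform_points(b, transform_points(a, p)))
  expect_equal(transform_points(composite_transform(), p), p)
})

test_that("transform inversion meets its residual contract", {
  dom <- grid_geometry(c(20, 20, 20), spacing = c(3, 3, 3))
  # identity inverts to (numerically) identity
  i0 <- invert_transform(affine_transform(), dom)
  expect_lt(max(abs(i0$disp)), 1e-12)
  # pure translation inverts to the negated translation
  it <- invert_transform(affine_transform(translation = c(4, -3, 2)), dom)
  pts <- grid_points(dom)
  expect_equal(transform_points(it, pts) - pts,
               matrix(rep(c(-4, 3, -2), each = nrow(pts)), ncol = 3),
               tolerance = 1e-8)
  # smooth random warp (coefficients <= 0.4 sigma) inverts within tolerance
  set.seed(9)
  bt <- bspline_lattice(dom, 20)
  bt$coef <- array(runif(length(bt$coef), -8, 8), dim(bt$coef))  # 0.4 * 20
  inv <- invert_transform(bt, dom, tol = 0.1, upsample = 2L)
  expect_lt(attr(inv, "residual"), 0.1)
  # a non-invertible target errors with the achieved residual
  bt$coef <- bt$coef * 8
  expect_error(invert_transform(bt, dom, tol = 0.1, max_iter = 10), "residual")
})

test_that("warp plus recovered inverse round-trips a smooth image", {
  set.seed(5)
  g <- grid_geometry(c(24, 24, 24), spacing = c(2, 2, 2))
  ax <- seq(0, 2 * pi, length.out = 24)
  img <- image_volume(outer(outer(sin(ax), cos(ax)), sin(ax / 2)) * 50 + 100,
                      g$spacing)
  bt <- bspline_lattice(g, 18)
  bt$coef <- array(runif(length(bt$coef), -5, 5), dim(bt$coef))
  inv <- invert_transform(bt, g, tol = 0.05)
  back <- resample(resample(img, bt), inv)
  interior <- array(FALSE, c(24, 24, 24))
  interior[5:20, 5:20, 5:20] <- TRUE
  expect_lt(mean(abs(back$data[interior] - img$data[interior])), 2)
})
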