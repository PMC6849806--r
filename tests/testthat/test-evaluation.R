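test_that("dice follows its closed form and conventions", {
  m <- function(v) array(as.logical(v), c(length(v), 1, 1))
  a <- m(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  b <- m(c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(dice(a, a), 1)                       # identical masks
  expect_equal(dice(a, m(c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0))), 0)  # disjoint
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))         # |a|=4, |b|=6, |inter|=3
  expect_equal(dice(m(0), m(0)), 1)                 # both empty
  expect_equal(dice(a, b), dice(b, a))              # symmetric
  expect_error(dice(a, array(TRUE, c(2, 2, 2))), "common grid")
})

test_that("dice decreases monotonically under stepwise erosion", {
  sph <- sphere_mask(c(24, 24, 24), c(12, 12, 12), 9)
  vals <- vapply(0:3, function(r) {
    if (r == 0) return(dice(sph, sph))
    d2 <- jointatlas:::cpp_edt_sq(!sph, dim(sph), c(1, 1, 1))
    eroded <- array(sph & d2 > r^2, dim(sph))
    dice(eroded, sph)
  }, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("extracted surfaces track analytic areas", {
  # single voxel: small closed mesh with positive area
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  ms <- extract_surface(sv)
  expect_gt(mesh_area(ms), 0)
  expect_gte(nrow(ms$faces), 4)
  # every edge of a closed mesh is shared by exactly two faces
  ed <- rbind(ms$faces[, 1:2], ms$faces[, 2:3], ms$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # axis-aligned box: area within 15% of the analytic box area
  b <- array(FALSE, c(24, 24, 24)); b[5:14, 5:12, 5:10] <- TRUE
  area_box <- 2 * (10 * 8 + 10 * 6 + 8 * 6)
  expect_lt(abs(mesh_area(extract_surface(b)) / area_box - 1), 0.15)
  # sphere radius 10 mm at 1 mm spacing: area within 5% of 4 pi r^2
  sph <- sphere_mask(c(31, 31, 31), c(16, 16, 16), 10)
  expect_lt(abs(mesh_area(extract_surface(sph)) / (4 * pi * 100) - 1), 0.05)
  expect_error(extract_surface(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("surface-to-surface distance is exact against a brute-force oracle", {
  sph <- sphere_mask(c(15, 15, 15), c(8, 8, 8), 5)
  mesh <- extract_surface(sph)
  expect_equal(s2s_distance(mesh, mesh), 0)
  set.seed(13)
  pts <- cbind(runif(40, 0, 15), runif(40, 0, 15), runif(40, 0, 15))
  fake <- structure(list(vertices = pts,
                         faces = matrix(seq_len(39), ncol = 3, byrow = TRUE)),
                    class = "surface_mesh")
  got <- jointatlas:::cpp_point_mesh_dist(pts, mesh$vertices, mesh$faces)
  want <- point_mesh_dist_brute(pts, mesh)
  expect_lt(max(abs(got - want)), 1e-9)
  expect_error(s2s_distance(mesh, list(vertices = pts[0, ], faces = fake$faces)),
               "empty")
})

test_that("s2s is directed: parallel patches and an asymmetric configuration", {
  # two parallel unit squares separated by d = 3
  quad <- function(z) list(vertices = rbind(c(0, 0, z), c(1, 0, z),
                                            c(1, 1, z), c(0, 1, z)),
                           faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  a <- structure(quad(0), class = "surface_mesh")
  b <- structure(quad(3), class = "surface_mesh")
  expect_equal(s2s_distance(a, b), 3)
  # a small patch vs a large plane: directed distances differ
  big <- structure(list(vertices = rbind(c(-10, -10, 0), c(10, -10, 0),
                                         c(10, 10, 0), c(-10, 10, 0)),
                        faces = rbind(c(1, 2, 3), c(1, 3, 4))),
                   class = "surface_mesh")
  off <- structure(list(vertices = rbind(c(30, 0, 4), c(31, 0, 4), c(30, 1, 4)),
                        faces = matrix(c(1, 2, 3), 1)),
                   class = "surface_mesh")
  expect_false(isTRUE(all.equal(s2s_distance(off, big), s2s_distance(big, off))))
  expect_equal(s2s_distance(off, big, symmetric = TRUE),
               (s2s_distance(off, big) + s2s_distance(big, off)) / 2)
})

test_that("evaluate reports per-structure and whole-LA accuracy", {
  spec <- tiny_phantom_spec(seed = 3)
  gt <- make_template(spec)$labels
  rep0 <- evaluate(gt, gt)
  expect_true(all(rep0$dice == 1))
  expect_true(all(rep0$s2s_mm[!rep0$skipped] == 0))
  expect_equal(rep0$structure[1], "whole_LA")
  # deleting one PV zeroes that structure only
  seg <- gt
  seg$data[seg$data == 4L] <- 0L
  rep1 <- evaluate(seg, gt)
  expect_equal(rep1$dice[rep1$structure == "RSPV"], 0)
  expect_true(all(rep1$dice[rep1$structure %in% c("LSPV", "LIPV", "RIPV",
                                                  "LA_chamber", "LAA")] == 1))
  # whole-LA Dice is the Dice of unions, not an average of per-label values
  u_seg <- array(seg$data != 0, dim(seg$data))
  u_gt <- array(gt$data != 0, dim(gt$data))
  expect_equal(rep1$dice[rep1$structure == "whole_LA"], dice(u_seg, u_gt))
  expect_error(evaluate(seg, label_volume(gt$data, gt$spacing, gt$origin,
                                          label_map = c(background = 0L, x = 1L,
                                                        a = 2L, b = 3L, c = 4L,
                                                        d = 5L, e = 6L))),
               "label map")
})

test_that("evaluate matches hand-computed overlaps on a constructed toy", {
  arr_gt <- array(0L, c(6, 6, 6))
  arr_gt[1:3, 1, 1] <- 1L     # 3 voxels chamber
  arr_gt[1:2, 2, 1] <- 2L     # 2 voxels LSPV
  arr_sg <- array(0L, c(6, 6, 6))
  arr_sg[2:4, 1, 1] <- 1L     # overlap 2 of 3
  arr_sg[1:2, 3, 1] <- 2L     # disjoint from gt LSPV
  gt <- label_volume(arr_gt)
  sg <- label_volume(arr_sg)
  rep <- evaluate(sg, gt)
  expect_equal(rep$dice[rep$structure == "LA_chamber"], 2 * 2 / (3 + 3))
  expect_equal(rep$dice[rep$structure == "LSPV"], 0)
  expect_equal(rep$dice[rep$structure == "whole_LA"], 2 * 2 / (5 + 5))
  # structures empty in both are flagged and get Dice 1
  expect_true(all(rep$skipped[rep$structure %in% c("LIPV", "RSPV", "RIPV", "LAA")]))
  expect_true(all(rep$dice[rep$skipped] == 1))
})

test_that("meshes serialize to PLY and STL", {
  sph <- sphere_mask(c(12, 12, 12), c(6, 6, 6), 4)
  mesh <- extract_surface(sph)
  ply <- tempfile(fileext = ".ply")
  stl <- tempfile(fileext = ".stl")
  write_mesh(mesh, ply)
  write_mesh(mesh, stl)
  hdr <- readLines(ply, n = 4)
  expect_equal(hdr[1], "ply")
  expect_match(hdr[3], as.character(nrow(mesh$vertices)))
  expect_match(readLines(stl, n = 1), "solid")
})
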