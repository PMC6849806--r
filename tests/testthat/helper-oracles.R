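# Independent oracles and small fixtures used across the suite.

# cubic B-spline basis written independently of the package internals
beta3_r <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# brute-force FFD displacement: sum over ALL control points
bspline_disp_brute <- function(bt, x) {
  u <- (x - bt$lattice_origin) / bt$grid_spacing
  ncp <- dim(bt$coef)[1:3]
  d <- c(0, 0, 0)
  for (i in seq_len(ncp[1]))
    for (j in seq_len(ncp[2]))
      for (k in seq_len(ncp[3])) {
        w <- beta3_r(u[1] - (i - 1)) * beta3_r(u[2] - (j - 1)) *
          beta3_r(u[3] - (k - 1))
        if (w != 0) d <- d + w * bt$coef[i, j, k, ]
      }
  d
}

# exact point-to-triangle distance, formulated independently of the C++
# closest-point routine: interior plane projection via normal equations,
# otherwise the minimum over the three edge segments
pt_tri_dist_r <- function(p, a, b, c) {
  u <- b - a; v <- c - a; w <- p - a
  M <- rbind(c(sum(u * u), sum(u * v)), c(sum(u * v), sum(v * v)))
  st <- tryCatch(solve(M, c(sum(w * u), sum(w * v))), error = function(e) c(-1, -1))
  if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
    q <- a + st[1] * u + st[2] * v
    return(sqrt(sum((p - q)^2)))
  }
  seg <- function(p, x, y) {
    d <- y - x
    t <- sum((p - x) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (x + t * d))^2))
  }
  min(seg(p, a, b), seg(p, b, c), seg(p, a, c))
}

point_mesh_dist_brute <- function(pts, mesh) {
  vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
      pt_tri_dist_r(pts[i, ], tri[1, ], tri[2, ], tri[3, ])
    }, 1))
  }, 1)
}

# small phantom for fast module tests (same physical anatomy, coarse grid)
tiny_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(48, 48, 32), spacing = c(2.5, 2.5, 4.54),
               seed = seed, ...)
}

# binary dilation by r voxels (index units)
dilate_mask <- function(mask, r) {
  d2 <- jointatlas:::cpp_edt_sq(mask, dim(mask), c(1, 1, 1))
  array(d2 <= r^2 + 1e-9, dim(mask))
}

sphere_mask <- function(n, center, radius, spacing = c(1, 1, 1)) {
  g <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  r2 <- ((g$i - center[1]) * spacing[1])^2 +
    ((g$j - center[2]) * spacing[2])^2 +
    ((g$k - center[3]) * spacing[3])^2
  array(r2 <= radius^2, n)
}

rolling_mean <- function(x, w) {
  if (length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[-seq_len(w - 1)]
}
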