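# a minimal aggregate map around given fused points, for estimator tests
fake_am <- function(points, R, mean_hull) {
  structure(list(mean = list(mean_hull = mean_hull), points = points,
                 replicate_id = rep("r1", nrow(points)),
                 clipped = rep(FALSE, nrow(points)), R = R,
                 n_i = c(r1 = nrow(points)), clip_count = 0, tps = list()),
            class = "aggregate_map")
}

test_that("voxelization covers the hull and measures its volume", {
  ball <- ellipsoid_boundary(c(1, 1, 1), n_theta = 64, n_phi = 64)
  g <- voxelize(ball, 64^3)
  expect_lt(abs(g$interior_volume / (4 * pi / 3) - 1), 0.02)
  # interior voxel centres are genuinely inside
  expect_true(all(point_in_hull(ball, g$interior_centres)))
  # at least one voxel of margin on every side
  expect_true(all(g$interior_idx[, 1] > 1 & g$interior_idx[, 1] < g$dims[1]))
  # refinement converges toward the hull volume
  small <- ellipsoid_boundary(c(1, 1, 1))
  err <- vapply(c(16^3, 32^3, 64^3), function(n)
    abs(voxelize(small, n)$interior_volume - small$volume), 0)
  expect_lt(err[3], err[1])
  expect_error(voxelize(ball, 50), "at least 100")
})

test_that("a single point owns everything: closed-form intensity", {
  ball <- ellipsoid_boundary(c(1, 1, 1))
  g <- voxelize(ball, 32^3)
  am <- fake_am(matrix(0, 1, 3), R = 4, ball)
  im <- estimate_intensity(am, g)
  vals <- im$values[g$interior_idx]
  expect_equal(unique(round(vals, 12)),
               round(1 / (4 * g$interior_volume), 12))
  expect_equal(sum(im$values) * g$voxel_size^3, 1 / 4, tolerance = 1e-12)
  expect_equal(im$csr_level, (1 / 4) / g$interior_volume)
})

test_that("mass conservation and brute-force ownership on a small grid", {
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  g <- voxelize(b, 24^3)
  set.seed(14)
  pts <- csr_in_hull(b, 100)
  am <- fake_am(pts, R = 10, b)
  im <- estimate_intensity(am, g)
  expect_lt(abs(sum(im$values) * g$voxel_size^3 - 100 / 10), 0.01 * 10)

  # exhaustive nearest-point loop as the oracle, lowest index wins ties
  owner <- nucleomap:::nearest_point_cpp(g$interior_centres, pts)
  oracle <- apply(g$interior_centres, 1, function(v) {
    d2 <- colSums((t(pts) - v)^2)
    which(d2 == min(d2))[1]
  })
  expect_identical(as.integer(owner), as.integer(oracle))
})

test_that("symmetric patterns give symmetric intensity maps", {
  cube <- convex_boundary(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))))
  g <- voxelize(cube, 20^3)
  am <- fake_am(rbind(c(-0.4, 0, 0), c(0.4, 0, 0)), R = 1, cube)
  im <- estimate_intensity(am, g)
  flipped <- im$values[, , rev(seq_len(g$dims[3]))]
  # mirror symmetry in x up to voxels cut by the symmetry plane
  keep <- abs(g$interior_centres[, 1]) > g$voxel_size
  arr_idx <- g$interior_idx[keep, , drop = FALSE]
  expect_equal(im$values[arr_idx], flipped[arr_idx], tolerance = 1e-9)
})

test_that("the CSR level matches the interior mean of a CSR intensity map", {
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  g <- voxelize(b, 24^3)
  set.seed(3)
  pts <- csr_in_hull(b, 2000)
  am <- fake_am(pts, R = 20, b)
  im <- estimate_intensity(am, g)
  expect_equal(mean(im$values[g$interior_idx]), im$csr_level, tolerance = 0.05)
  expect_equal(csr_level(am, g), (2000 / 20) / g$interior_volume)
})

test_that("intensity fluctuation at fixed spatial scale shrinks with point count", {
  # the per-voxel Voronoi estimate is scale-free in n (one cell per voxel),
  # so consistency shows up at a fixed spatial scale: average over 4^3-voxel
  # blocks and watch the between-block CV fall as points accumulate
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  g <- voxelize(b, 24^3)
  block_cv <- function(v, k = 4) {
    bi <- (g$interior_idx - 1) %/% k
    key <- bi[, 1] + 100 * bi[, 2] + 10000 * bi[, 3]
    means <- tapply(v, key, mean)
    cnt <- tapply(v, key, length)
    m <- means[cnt >= k^3 / 2] # mostly-interior blocks only
    stats::sd(m) / mean(m)
  }
  cv <- vapply(c(50, 500, 5000), function(n) {
    set.seed(100 + n)
    im <- estimate_intensity(fake_am(csr_in_hull(b, n), R = 1, b), g)
    block_cv(im$values[g$interior_idx])
  }, 0)
  expect_true(all(diff(cv) < 0))
})

test_that("natural-neighbour smoothing preserves mass and positivity", {
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  g <- voxelize(b, 20^3)
  set.seed(5)
  am <- fake_am(csr_in_hull(b, 60), R = 5, b)
  raw <- estimate_intensity(am, g)
  sm <- estimate_intensity(am, g, smooth = TRUE)
  expect_equal(sum(sm$values), sum(raw$values), tolerance = 1e-9)
  expect_true(all(sm$values >= 0))
  expect_false(identical(sm$values, raw$values))
  # smoothing reduces spatial roughness
  expect_lt(stats::sd(sm$values[g$interior_idx]),
            stats::sd(raw$values[g$interior_idx]))
})

test_that("zero fused points give a zero map with a warning", {
  b <- ellipsoid_boundary(c(1, 1, 1))
  g <- voxelize(b, 16^3)
  am <- fake_am(matrix(numeric(0), 0, 3), R = 3, b)
  expect_warning(im <- estimate_intensity(am, g), "no points")
  expect_true(all(im$values == 0))
  expect_equal(im$csr_level, 0)
})
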