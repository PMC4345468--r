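# minimal grid + intensity objects built by hand
toy_grid <- function(n = 8, vs = 1) {
  mask <- array(TRUE, dim = c(n, n, n))
  idx <- as.matrix(expand.grid(k = 1:n, j = 1:n, i = 1:n))
  structure(list(origin = c(0, 0, 0), voxel_size = vs, dims = c(n, n, n),
                 interior_mask = mask, interior_idx = idx,
                 interior_centres = cbind((idx[, 3] - 0.5) * vs,
                                          (idx[, 2] - 0.5) * vs,
                                          (idx[, 1] - 0.5) * vs),
                 interior_volume = n^3 * vs^3),
            class = "voxel_grid")
}

toy_intensity <- function(values, grid, lam0) {
  structure(list(grid = grid, values = values, csr_level = lam0),
            class = "intensity_map")
}

test_that("excess maps subtract the CSR level and clamp at zero", {
  g <- toy_grid(4)
  vals <- array(2, dim = g$dims)
  im <- toy_intensity(vals, g, 2)
  expect_true(all(excess_map(im, "aggregated") == 0))
  expect_true(all(excess_map(im, "dispersed") == 0))

  vals[2, 2, 2] <- 4
  im2 <- toy_intensity(vals, g, 2)
  ex <- excess_map(im2, "aggregated")
  expect_equal(ex[2, 2, 2], 2)
  expect_equal(sum(ex), 2)

  # the two directions are never simultaneously positive
  set.seed(2)
  vals3 <- array(rnorm(64, 2), dim = g$dims)
  im3 <- toy_intensity(vals3, g, 2)
  both <- excess_map(im3, "aggregated") > 0 & excess_map(im3, "dispersed") > 0
  expect_false(any(both))
})

test_that("cluster-size enhancement equals component volume", {
  g <- toy_grid(8, vs = 0.5)
  ex <- array(0, dim = g$dims)
  ex[2, 2, 2] <- 1
  en <- cluster_enhance(ex, g, mode = "cluster_size")
  expect_equal(en$statistic[2, 2, 2], 0.5^3)
  expect_equal(sum(en$statistic > 0), 1)

  # face-sharing pair: joint under 6; corner-sharing: split under 6, joint 26
  ex2 <- array(0, dim = g$dims)
  ex2[2, 2, 2] <- 1; ex2[3, 2, 2] <- 2
  en2 <- cluster_enhance(ex2, g, connectivity = 6, mode = "cluster_size")
  expect_equal(en2$statistic[2, 2, 2], 2 * 0.5^3)
  ex3 <- array(0, dim = g$dims)
  ex3[2, 2, 2] <- 1; ex3[3, 3, 3] <- 1
  en6 <- cluster_enhance(ex3, g, connectivity = 6, mode = "cluster_size")
  en26 <- cluster_enhance(ex3, g, connectivity = 26, mode = "cluster_size")
  expect_equal(en6$statistic[2, 2, 2], 0.5^3)
  expect_equal(en26$statistic[2, 2, 2], 2 * 0.5^3)
  expect_error(cluster_enhance(ex3, g, connectivity = 5), "connectivity")
})

test_that("TFCE: flat-top profile integrates to volume x height when E=1, H=0", {
  g <- toy_grid(8)
  ex <- array(0, dim = g$dims)
  ex[3:5, 3:6, 2:4] <- 0.8          # 3*4*3 = 36 voxels, height 0.8
  en <- cluster_enhance(ex, g, mode = "tfce", E = 1, H = 0, dh = 0.8 / 40)
  expect_equal(en$statistic[4, 4, 3], 36 * 0.8, tolerance = 1e-9)
  expect_true(all(en$statistic[ex == 0] == 0))
})

test_that("TFCE matches a brute-force threshold sweep", {
  g <- toy_grid(8)
  set.seed(7)
  ex <- array(pmax(rnorm(512, 0.1, 0.5), 0), dim = g$dims)
  dh <- max(ex) / 30
  en <- cluster_enhance(ex, g, connectivity = 6, mode = "tfce",
                        E = 0.5, H = 2, dh = dh)
  oracle <- array(0, dim = g$dims)
  for (h in seq(dh, max(ex), by = dh)) {
    lab <- nucleomap:::label3d_cpp(ex >= h, 6L)
    sizes <- tabulate(lab)
    pos <- lab > 0
    oracle[pos] <- oracle[pos] + (sizes[lab[pos]])^0.5 * h^2 * dh
  }
  expect_equal(en$statistic, oracle, tolerance = 1e-9)
})

test_that("Monte-Carlo p-values follow the (1+k)/(M+1) convention with ties", {
  null <- c(0, 1, 1, 2, 5)
  stat <- c(0, 1, 1.5, 2, 6)
  p <- nucleomap:::mc_pvalue(stat, null)
  naive <- vapply(stat, function(s) (1 + sum(null >= s)) / (length(null) + 1), 0)
  expect_equal(p, naive)
  expect_true(all(p > 0))
})

test_that("null simulation is seeded, validated, and deterministic", {
  reps <- gt_cohort(6, n_points = 5, seed = 51)
  res <- analyse_cohort(reps, n_rings = 5, n_per_ring = 8,
                        grid_target = 16^3, M = 19, alpha = 0.05, seed = 3)
  n1 <- simulate_null(res$am, res$oriented_boundaries, res$grid, M = 25, seed = 9)
  n2 <- simulate_null(res$am, res$oriented_boundaries, res$grid, M = 25, seed = 9)
  expect_identical(n1$max_aggregated, n2$max_aggregated)
  expect_identical(n1$max_dispersed, n2$max_dispersed)
  n3 <- simulate_null(res$am, res$oriented_boundaries, res$grid, M = 25, seed = 10)
  expect_false(identical(n1$max_aggregated, n3$max_aggregated))
  expect_error(simulate_null(res$am, res$oriented_boundaries, res$grid, M = 0),
               "M must be")
  expect_error(simulate_null(res$am, res$oriented_boundaries[-1], res$grid,
                             M = 5), "inconsistent")
})

test_that("significance maps reject by the null-maximum rule, monotonically", {
  g <- toy_grid(6)
  stat <- array(0, dim = g$dims)
  en0 <- structure(list(grid = g, direction = "aggregated",
                        excess = stat, statistic = stat),
                   class = "enhanced_map")
  null <- structure(list(max_aggregated = 1:199 / 10,
                         max_dispersed = 1:199 / 10, M = 199L, seed = 1),
                    class = "null_samples")
  sig0 <- significance_maps(list(aggregated = en0, dispersed = en0), null)
  expect_false(any(sig0$reject_aggregated))
  expect_false(any(sig0$reject_dispersed))

  set.seed(12)
  stat1 <- array(stats::runif(216, 0, 25), dim = g$dims)
  en1 <- en0; en1$statistic <- stat1; en1$excess <- stat1
  sig1 <- significance_maps(list(aggregated = en1, dispersed = en0), null)
  expect_true(sig1$reject_aggregated[which.max(stat1)])
  # monotone: every voxel with statistic >= a rejecting voxel's also rejects
  thr <- min(stat1[sig1$reject_aggregated])
  expect_true(all(sig1$reject_aggregated[stat1 >= thr]))
  expect_false(any(sig1$reject_aggregated[stat1 < thr]))

  expect_error(significance_maps(list(aggregated = en1, dispersed = en0),
                                 null, alpha = 0.7), "alpha")
  small <- null; small$M <- 5L
  small$max_aggregated <- small$max_dispersed <- 1:5
  expect_error(significance_maps(list(aggregated = en1, dispersed = en0),
                                 small, alpha = 0.05), "resolve")
})

test_that("p-values are valid under the CSR null (small calibration loop)", {
  # tiny but real: the observed max statistic is exchangeable with its nulls
  pvals <- vapply(1:12, function(c) {
    reps <- gt_cohort(8, n_points = 6, seed = child_seed(600, c))
    res <- analyse_cohort(reps, n_rings = 5, n_per_ring = 8,
                          grid_target = 16^3, M = 39, alpha = 0.05,
                          seed = child_seed(700, c))
    min(res$sig$p_aggregated)
  }, 0)
  # P(min p <= 0.05) is at most 0.05 per cohort: seeing 3+ of 12 would be
  # a < 2% event; this catches gross miscalibration only
  expect_lte(sum(pvals <= 0.05), 2)
})
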