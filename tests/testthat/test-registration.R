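# random configurations with a minimum separation, as real landmark sets
# have: near-coincident landmarks make the TPS kernel ill-conditioned and
# are impossible by construction in ray-cast landmark placement
random_landmarks <- function(seed, L = 30) {
  set.seed(seed)
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < L) {
    cand <- csr_in_hull(b, 1)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= 0.25)
      pts <- rbind(pts, cand)
  }
  pts
}

test_that("TPS with identical source and target is the identity", {
  S <- random_landmarks(1)
  tps <- fit_tps(S, S)
  expect_equal(tps$weights, matrix(0, nrow(S), 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tps$affine[2:4, ], diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  P <- random_landmarks(2, 50)
  expect_equal(tps_apply(tps, P), P, tolerance = 1e-8)
})

test_that("TPS reproduces similarity and affine maps with zero kernel weights", {
  S <- random_landmarks(3)
  R <- nucleomap:::rot_z(0.7)
  sim <- function(X) 1.7 * X %*% t(R) + matrix(c(1, -2, 0.5), nrow(X), 3,
                                               byrow = TRUE)
  tps <- fit_tps(S, sim(S))
  expect_lt(max(abs(tps$weights)), 1e-8)
  P <- random_landmarks(4, 200)
  expect_equal(tps_apply(tps, P), sim(P), tolerance = 1e-7)

  A <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  aff <- function(X) X %*% t(A) + matrix(c(0.3, 0, -1), nrow(X), 3, byrow = TRUE)
  tps2 <- fit_tps(S, aff(S))
  expect_lt(max(abs(tps2$weights)), 1e-8)
  expect_equal(tps_apply(tps2, P), aff(P), tolerance = 1e-7)
})

test_that("TPS interpolates exactly and satisfies its side conditions", {
  # random pairs are worse conditioned than ray-cast surface landmark sets
  # (which interpolate to < 1e-8 of the diameter; see the validation suite),
  # so the bound here reflects the conditioning of arbitrary configurations
  for (seed in c(5, 6)) {
    S <- random_landmarks(seed)
    T_ <- random_landmarks(seed + 10)
    tps <- fit_tps(S, T_)
    diam <- sqrt(sum((apply(T_, 2, max) - apply(T_, 2, min))^2))
    expect_lt(max(abs(tps_apply(tps, S) - T_)), 1e-7 * diam)
    expect_lt(max(abs(colSums(tps$weights))), 1e-8)
    expect_lt(max(abs(t(S) %*% tps$weights)), 1e-7)
  }
  expect_error(fit_tps(random_landmarks(1)[1:4, ], random_landmarks(2)[1:4, ]),
               "at least 5")
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(fit_tps(flat, random_landmarks(7, 10), replicate_id = "rX"),
               "rX")
})

test_that("warping preserves point order and handles the identity", {
  S <- random_landmarks(8)
  tps <- fit_tps(S, S)
  b <- ellipsoid_boundary(c(2, 1.5, 1))
  set.seed(9); pts <- csr_in_hull(b, 40)
  pat <- point_pattern(pts)
  w <- warp_points(tps, pat, b)
  expect_equal(w$points, pts, tolerance = 1e-8)
  expect_false(any(w$clipped))
  # order independence
  perm <- sample(40)
  w2 <- warp_points(tps, point_pattern(pts[perm, ]), b)
  expect_equal(w2$points, w$points[perm, ], tolerance = 1e-12)
})

test_that("interior stays interior: clip rate is tiny for polytope-drawn CSR", {
  reps <- gt_cohort(8, seed = 23)
  oriented <- nucleomap:::orient_cohort(reps, 9, 16, NULL)
  ms <- gpa_mean_shape(oriented$landmark_sets)
  am <- build_aggregate_map(oriented$landmark_sets, oriented$patterns, ms)
  set.seed(1)
  n_out <- 0; n_tot <- 0
  for (id in names(am$tps)) {
    poly <- convex_boundary(oriented$landmark_sets[[id]]$landmarks)
    p <- csr_in_hull(poly, 1250)
    w <- tps_apply(am$tps[[id]], p)
    n_out <- n_out + sum(!point_in_hull(ms$mean_hull, w))
    n_tot <- n_tot + nrow(p)
  }
  expect_lt(n_out / n_tot, 0.01)
})

test_that("the aggregate map fuses, tags and counts correctly", {
  reps <- gt_cohort(4, seed = 29)
  counts <- c(3, 5, 0, 2)
  for (i in 1:4) {
    reps[[i]]$pattern <- sample_pattern(reps[[i]]$boundary,
                                        pattern_spec("csr", counts[i], seed = i),
                                        reps[[i]]$replicate_id)
  }
  oriented <- nucleomap:::orient_cohort(reps, 9, 16, NULL)
  ms <- gpa_mean_shape(oriented$landmark_sets)
  am <- build_aggregate_map(oriented$landmark_sets, oriented$patterns, ms)
  expect_equal(am$R, 4)
  expect_equal(unname(am$n_i), counts)
  expect_equal(nrow(am$points), sum(counts))
  expect_equal(table(factor(am$replicate_id,
                            levels = names(am$n_i)))[["r003"]], 0)
  # warping each replicate's own landmarks reproduces the mean landmarks
  for (id in names(am$tps))
    expect_equal(tps_apply(am$tps[[id]], am$tps[[id]]$source),
                 ms$mean_landmarks, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(build_aggregate_map(list(), list(), ms), "no replicates")
})

test_that("identical replicates yield identical warped patterns", {
  b <- generate_boundary(shape_spec(c(8, 6, 2.5), 0, 0.3, seed = 44))
  pat <- sample_pattern(b, pattern_spec("csr", 7, seed = 2))
  reps <- lapply(1:3, function(i)
    list(boundary = b, pattern = point_pattern(pat$points, sprintf("r%d", i)),
         replicate_id = sprintf("r%d", i)))
  oriented <- nucleomap:::orient_cohort(reps, 9, 16, NULL)
  ms <- gpa_mean_shape(oriented$landmark_sets)
  am <- build_aggregate_map(oriented$landmark_sets, oriented$patterns, ms)
  w <- split.data.frame(am$points, am$replicate_id)
  expect_equal(w[[1]], w[[2]], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(w[[1]], w[[3]], tolerance = 1e-9, ignore_attr = TRUE)
})
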