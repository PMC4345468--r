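test_that("tip detection: symmetric ellipsoid resolves ties deterministically", {
  b <- ellipsoid_boundary(c(10, 7, 3))
  t1 <- find_ovoid_tip(b)
  t2 <- find_ovoid_tip(b)
  expect_identical(t1, t2)
  # tie-break lands on the +major-axis end
  expect_equal(abs(t1$direction[1]), 1, tolerance = 1e-6)
  expect_equal(t1$direction[3], 0)
  expect_gt(t1$direction[1], 0)
})

test_that("tip detection finds the sharpened end across random rotations", {
  angles <- vapply(1:20, function(s) {
    b <- generate_boundary(shape_spec(c(8, 6, 2.5), 0, 0.3, seed = s))
    truth <- attr(b, "truth")$tip_direction
    tip <- find_ovoid_tip(b)
    acos(pmin(1, sum(tip$direction * truth))) * 180 / pi
  }, 0)
  expect_lt(max(angles), 15)
})

test_that("manual tip override bypasses detection", {
  b <- ellipsoid_boundary(c(10, 7, 3))
  tip <- find_ovoid_tip(b, tip_override = c(0, 1))
  expect_equal(tip$direction, c(0, 1, 0))
  expect_error(find_ovoid_tip(b, tip_override = c(0, 0)), "zero")
})

test_that("orientation rotates about z only, never reflects, and composes", {
  b <- generate_boundary(shape_spec(c(8, 6, 2.5), 0, 0.3, seed = 2))
  tip <- find_ovoid_tip(b)
  ori <- orient_nucleus(b, tip$direction)
  expect_equal(det(ori$rotation), 1, tolerance = 1e-12)
  expect_equal(ori$rotation[3, ], c(0, 0, 1))           # z axis preserved
  expect_equal(as.numeric(ori$boundary$centroid), c(0, 0, 0), tolerance = 1e-9)
  # the tip direction maps to +x
  d <- as.numeric(ori$rotation %*% tip$direction)
  expect_equal(d, c(1, 0, 0), tolerance = 1e-9)

  # a prior z-rotation changes nothing about the oriented result
  b2 <- nucleomap:::transform_boundary(b, nucleomap:::rot_z(1.1), c(3, -2, 0.5))
  ori2 <- orient_nucleus(b2, find_ovoid_tip(b2)$direction)
  expect_equal(ori2$boundary$vertices, ori$boundary$vertices, tolerance = 1e-9)

  # tip already along +x: identity rotation
  orix <- orient_nucleus(ori$boundary, c(1, 0, 0))
  expect_equal(orix$rotation, diag(3), tolerance = 1e-12)
})

test_that("landmarks: sphere closed form, surface residual, pipeline invariance", {
  s <- ellipsoid_boundary(c(1, 1, 1), n_theta = 64, n_phi = 64)
  lm <- place_landmarks(s, n_rings = 1, n_per_ring = 4)
  expect_equal(nrow(lm$landmarks), 6)
  expect_equal(lm$landmarks[1, ], c(1, 0, 0), tolerance = 1e-3)
  expect_equal(lm$landmarks[6, ], c(-1, 0, 0), tolerance = 1e-3)
  r <- sqrt(rowSums(lm$landmarks^2))
  expect_equal(r, rep(1, 6), tolerance = 5e-3)      # inscribed-hull sagitta
  eq <- lm$landmarks[2:5, ]
  expect_equal(eq[, 1], rep(0, 4), tolerance = 1e-9) # equatorial ring
  ang <- atan2(eq[, 2], eq[, 3])
  expect_equal(sort(diff(sort(ang))), rep(pi / 2, 3), tolerance = 1e-6)

  # landmarks sit on the hull surface to high precision
  b <- generate_boundary(shape_spec(c(8, 6, 2.5), 0.05, 0.3, seed = 4))
  ori <- orient_nucleus(b, find_ovoid_tip(b)$direction)
  lmb <- place_landmarks(ori$boundary)
  expect_lt(max(abs(nucleomap:::hull_margin(ori$boundary, lmb$landmarks))),
            1e-6 * nucleomap:::hull_diameter(ori$boundary))

  # rotating the input, then orienting, yields identical landmarks
  b2 <- nucleomap:::transform_boundary(b, nucleomap:::rot_z(2.2), c(1, 4, 0))
  ori2 <- orient_nucleus(b2, find_ovoid_tip(b2)$direction)
  lmb2 <- place_landmarks(ori2$boundary)
  expect_equal(lmb2$landmarks, lmb$landmarks, tolerance = 1e-6)

  # ray casting needs an interior origin
  shifted <- nucleomap:::transform_boundary(ori$boundary, diag(3), c(50, 0, 0))
  expect_error(place_landmarks(shifted), "origin")
})

test_that("GPA recovers a shape exactly from similarity-transformed copies", {
  b <- generate_boundary(shape_spec(c(8, 6, 2.5), 0, 0.3, seed = 6))
  ori <- orient_nucleus(b, find_ovoid_tip(b)$direction)
  lm <- place_landmarks(ori$boundary)$landmarks
  set.seed(3)
  sets <- lapply(1:6, function(i) {
    s <- runif(1, 0.5, 2)
    th <- runif(1, 0, 2 * pi)
    as_landmark_set(s * lm %*% t(nucleomap:::rot_z(th)) +
                      matrix(rnorm(3), nrow(lm), 3, byrow = TRUE),
                    sprintf("r%d", i))
  })
  ms <- gpa_mean_shape(sets)
  expect_true(ms$converged)
  expect_lt(procrustes_distance(ms$mean_landmarks, lm), 1e-8)
  expect_equal(colMeans(ms$mean_landmarks), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(ms$mean_landmarks^2)), 1, tolerance = 1e-9)
  expect_true(all(diff(ms$objective_trace) <= 1e-9))
})

test_that("GPA: two-shape symmetry, order invariance, input validation", {
  c1 <- gt_cohort(5, seed = 31)
  oriented <- nucleomap:::orient_cohort(c1, 5, 8, NULL)
  sets <- oriented$landmark_sets
  ms2 <- gpa_mean_shape(sets[1:2])
  d <- vapply(1:2, function(i)
    procrustes_distance(sets[[i]]$landmarks, ms2$mean_landmarks), 0)
  expect_lt(abs(d[1] - d[2]), 1e-8)

  ms <- gpa_mean_shape(sets)
  msr <- gpa_mean_shape(rev(sets))
  expect_lt(procrustes_distance(ms$mean_landmarks, msr$mean_landmarks), 1e-6)
  expect_true(all(diff(ms$objective_trace) <= 1e-9))

  expect_error(gpa_mean_shape(sets[1]), "at least 2")
  bad <- sets
  bad[[2]]$landmarks <- bad[[2]]$landmarks[-1, ]
  expect_error(gpa_mean_shape(bad), "mismatched")
})

test_that("Procrustes rotations are proper rotations", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    R <- nucleomap:::procrustes_rotation(X, Y)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("the mean shape of jittered ellipsoid cohorts has the mean proportions", {
  reps <- gt_cohort(50, seed = 17)
  oriented <- nucleomap:::orient_cohort(reps, 9, 16, NULL)
  ms <- gpa_mean_shape(oriented$landmark_sets)
  rng <- apply(ms$mean_hull$vertices, 2, function(v) diff(range(v)))
  # template semi-axes 7, 5.5, 2.2 (sharpened by 0.3 along +x): compare the
  # aspect ratios of the size-normalized mean to the template's
  expected <- c(7 * (2 + 0.3) / 2, 5.5, 2.2)
  expect_equal(rng / rng[2], expected / expected[2], tolerance = 0.05)
})
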