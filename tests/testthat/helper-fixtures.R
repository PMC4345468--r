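# Shared fixture builders: everything is generated in code at test time.

# convex boundary from exact samples of a sphere / axis-aligned ellipsoid
ellipsoid_boundary <- function(semi_axes = c(1, 1, 1), n_theta = 32,
                               n_phi = 32) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  dirs <- rbind(c(1, 0, 0),
                cbind(cos(g$theta), sin(g$theta) * cos(g$phi),
                      sin(g$theta) * sin(g$phi)),
                c(-1, 0, 0))
  convex_boundary(dirs %*% diag(semi_axes))
}

# unit cube boundary with vertices at (0/1)^3
cube_boundary <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  convex_boundary(v)
}

# landmark_set wrapper around a bare matrix
as_landmark_set <- function(m, id = "r1") {
  structure(list(landmarks = m, replicate_id = id), class = "landmark_set")
}

# ground-truth replicate list for analyse_cohort, skipping rendering
gt_cohort <- function(n, model = "csr", n_points = 8, seed = 1, ...) {
  generate_cohort(n, pattern = pattern_spec(model, n_points = n_points, ...),
                  seed = seed, render = FALSE)
}

# CSR pattern thinned to a minimum pairwise separation: splitting touching
# compartments is out of scope for segmentation, so fidelity fixtures must
# use resolvable ground truth
separated_pattern <- function(boundary, n, min_dist, seed) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- csr_in_hull(boundary, 1)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_dist)
      pts <- rbind(pts, cand)
  }
  point_pattern(pts)
}

# physical centres of rejecting voxels of a significance map
rejection_centres <- function(sig, direction = "aggregated") {
  w <- which(sig[[paste0("reject_", direction)]], arr.ind = TRUE)
  g <- sig$grid
  cbind(g$origin[1] + (w[, 3] - 0.5) * g$voxel_size,
        g$origin[2] + (w[, 2] - 0.5) * g$voxel_size,
        g$origin[3] + (w[, 1] - 0.5) * g$voxel_size)
}

# mean centroid-to-vertex distance, the "hull radius" used in power checks
hull_radius <- function(boundary) {
  mean(sqrt(rowSums(sweep(boundary$vertices, 2, boundary$centroid)^2)))
}
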