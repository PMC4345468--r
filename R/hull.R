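# ConvexBoundary: triangulated convex hull in physical coordinates, the
# spatial domain of one replicate nucleus.

#' Construct a convex boundary from a 3D point cloud
#'
#' Computes the convex hull of `points` and returns a `convex_boundary`
#' object: hull vertices, outward-oriented triangular facets, the volume
#' centroid and the enclosed volume. All geometry downstream (containment,
#' ray casting, fractional radius, uniform sampling) works off this object.
#'
#' @param points n x 3 numeric matrix of (x, y, z) coordinates, n >= 4,
#'   spanning 3D.
#' @return An object of class `convex_boundary` with fields `vertices`
#'   (v x 3), `faces` (m x 3 indices into `vertices`), `normals` (m x 3
#'   outward unit normals), `offsets` (m, plane offsets so that a facet is
#'   `normal . x = offset`), `centroid` (volume centroid), and `volume`.
#' @export
convex_boundary <- function(points) {
  points <- as_points(points)
  h <- convex_hull3_cpp(points)
  keep <- h$vertices
  remap <- integer(nrow(points))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[h$faces], ncol = 3)
  verts <- points[keep, , drop = FALSE]

  v0 <- verts[faces[, 1], , drop = FALSE]
  v1 <- verts[faces[, 2], , drop = FALSE]
  v2 <- verts[faces[, 3], , drop = FALSE]
  # signed tetra volumes from the coordinate origin; outward orientation
  # makes the sum the enclosed volume for any origin
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  w <- rowSums(v0 * cr) / 6
  volume <- sum(w)
  if (!is.finite(volume) || volume <= 0)
    stop("degenerate boundary: non-positive hull volume")
  tc <- (v0 + v1 + v2) / 4 # tetra centroid, 4th vertex is the origin
  centroid <- colSums(tc * w) / volume

  b <- structure(list(vertices = verts, faces = faces, normals = h$normals,
                      offsets = as.numeric(h$offsets), centroid = centroid,
                      volume = volume),
                 class = "convex_boundary")
  b$sampler <- hull_sampler(b)
  b
}

# precomputed centroid-fan tetrahedral decomposition used by csr_in_hull
hull_sampler <- function(b) {
  A <- b$vertices[b$faces[, 1], , drop = FALSE]
  B <- b$vertices[b$faces[, 2], , drop = FALSE]
  C <- b$vertices[b$faces[, 3], , drop = FALSE]
  O <- matrix(b$centroid, nrow(A), 3, byrow = TRUE)
  list(A = A, B = B, C = C,
       w = rowSums((A - O) * cross3(B - O, C - O)))
}

#' @export
print.convex_boundary <- function(x, ...) {
  cat(sprintf("convex_boundary: %d vertices, %d facets, volume %.4g\n",
              nrow(x$vertices), nrow(x$faces), x$volume))
  invisible(x)
}

# largest signed facet-plane excess per point: <= 0 inside, > 0 outside
hull_margin <- function(boundary, points) {
  points <- as_points(points)
  H <- rbind(t(boundary$normals), boundary$offsets)
  n <- nrow(points)
  # chunk so the n x m excess matrix stays bounded in memory
  block <- max(1L, 4e6 %/% ncol(H))
  if (n <= block) {
    ex <- cbind(points, -1) %*% H
    return(ex[cbind(seq_len(n), max.col(ex, ties.method = "first"))])
  }
  out <- numeric(n)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    ex <- cbind(points[s:e, , drop = FALSE], -1) %*% H
    out[s:e] <- ex[cbind(seq_len(e - s + 1), max.col(ex, ties.method = "first"))]
  }
  out
}

#' Test points for containment in a convex boundary
#'
#' @param boundary a `convex_boundary`.
#' @param points n x 3 point matrix.
#' @param tol slack on the facet half-space test, in length units; the
#'   default admits points within `1e-9` of the hull diameter.
#' @return Logical vector of length n.
#' @export
point_in_hull <- function(boundary, points, tol = 1e-9 * hull_diameter(boundary)) {
  hull_margin(boundary, points) <= tol
}

#' @rdname point_in_hull
#' @export
hull_diameter <- function(boundary) {
  rng <- apply(boundary$vertices, 2, range)
  vnorm(rng[2, ] - rng[1, ])
}

# distance from `origin` to the hull surface along each unit direction in
# `dirs` (n x 3); origin must be strictly interior
ray_exit <- function(boundary, origin, dirs) {
  dirs <- as_points(dirs)
  nd <- dirs %*% t(boundary$normals)                  # n x m
  no <- as.numeric(boundary$normals %*% origin)       # m
  tt <- sweep(1 / nd, 2, boundary$offsets - no, "*")  # (d - n.o) / (n.dir)
  tt[nd <= 0] <- Inf
  out <- tt[cbind(seq_len(nrow(tt)), max.col(-tt, ties.method = "first"))]
  if (any(!is.finite(out) | out <= 0))
    stop("ray casting failed: origin not strictly interior")
  out
}

#' Shape-normalized radial coordinate of points in a convex boundary
#'
#' The fractional radius of a point is its distance from the reference
#' origin (default: the volume centroid) divided by the distance from the
#' origin to the hull surface along the same ray: 0 at the origin, 1 on the
#' boundary regardless of nuclear shape.
#'
#' @param boundary a `convex_boundary`.
#' @param points n x 3 point matrix.
#' @param origin reference interior point.
#' @return Numeric vector of fractional radii.
#' @export
fractional_radius <- function(boundary, points, origin = boundary$centroid) {
  points <- as_points(points)
  rel <- sweep(points, 2, origin)
  r <- sqrt(rowSums(rel^2))
  out <- numeric(nrow(points))
  nz <- r > 0
  if (any(nz)) {
    dirs <- rel[nz, , drop = FALSE] / r[nz]
    out[nz] <- r[nz] / ray_exit(boundary, origin, dirs)
  }
  out
}

#' Sample uniform (CSR) points inside a convex boundary
#'
#' Exact uniform sampling via the fan decomposition of the hull into
#' tetrahedra about its centroid: a tetrahedron is chosen with probability
#' proportional to its volume and a point drawn uniformly inside it
#' (Rocchini-Cignoni folding). Uses the current RNG state, consuming a
#' fixed number of draws per point.
#'
#' @param boundary a `convex_boundary`.
#' @param n number of points.
#' @return n x 3 matrix of points inside the hull.
#' @export
csr_in_hull <- function(boundary, n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  smp <- boundary$sampler %||% hull_sampler(boundary)
  A <- smp$A; B <- smp$B; C <- smp$C; O <- boundary$centroid
  f <- sample.int(nrow(A), n, replace = TRUE, prob = smp$w)
  s <- runif(n); t <- runif(n); u <- runif(n)
  # fold the unit cube into the unit tetrahedron (Rocchini & Cignoni)
  flip <- s + t > 1
  s[flip] <- 1 - s[flip]; t[flip] <- 1 - t[flip]
  f2 <- t + u > 1
  t2 <- ifelse(f2, 1 - u, t); u2 <- ifelse(f2, 1 - s - t, u)
  f3 <- !f2 & (s + t + u > 1)
  s3 <- ifelse(f3, 1 - t2 - u2, s)
  u3 <- ifelse(f3, s + t + u - 1, u2)
  s <- s3; t <- t2; u <- u3
  Of <- matrix(O, n, 3, byrow = TRUE)
  Of + s * (A[f, , drop = FALSE] - Of) + t * (B[f, , drop = FALSE] - Of) +
    u * (C[f, , drop = FALSE] - Of)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# closest point on each triangle (rows of A, B, C) to the single point p,
# vectorized over triangles [Ericson, Real-Time Collision Detection, 5.1.5]
closest_on_triangles <- function(p, A, B, C) {
  AB <- B - A; AC <- C - A
  AP <- sweep(-A, 2, -p); BP <- sweep(-B, 2, -p); CP <- sweep(-C, 2, -p)
  d1 <- rowSums(AB * AP); d2 <- rowSums(AC * AP)
  d3 <- rowSums(AB * BP); d4 <- rowSums(AC * BP)
  d5 <- rowSums(AB * CP); d6 <- rowSums(AC * CP)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  # first matching Voronoi region wins; assign in descending priority
  region <- rep(7L, nrow(A))
  region[va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0] <- 6L
  region[vb <= 0 & d2 >= 0 & d6 <= 0] <- 5L
  region[d6 >= 0 & d5 <= d6] <- 4L
  region[vc <= 0 & d1 >= 0 & d3 <= 0] <- 3L
  region[d3 >= 0 & d4 <= d3] <- 2L
  region[d1 <= 0 & d2 <= 0] <- 1L
  out <- matrix(0, nrow(A), 3)
  r <- region == 1L
  out[r, ] <- A[r, ]
  r <- region == 2L
  out[r, ] <- B[r, ]
  r <- region == 3L
  w <- d1 / (d1 - d3)
  out[r, ] <- A[r, , drop = FALSE] + w[r] * AB[r, , drop = FALSE]
  r <- region == 4L
  out[r, ] <- C[r, ]
  r <- region == 5L
  w <- d2 / (d2 - d6)
  out[r, ] <- A[r, , drop = FALSE] + w[r] * AC[r, , drop = FALSE]
  r <- region == 6L
  w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  out[r, ] <- B[r, , drop = FALSE] + w[r] * (C - B)[r, , drop = FALSE]
  r <- region == 7L
  den <- va + vb + vc
  out[r, ] <- A[r, , drop = FALSE] +
    (vb / den)[r] * AB[r, , drop = FALSE] + (vc / den)[r] * AC[r, , drop = FALSE]
  out
}

# nearest point on the hull surface for each row of `points`; points that
# barely violate one facet (the common case when clipping warped centres)
# take a fast path: orthogonal projection onto the most-violated facet
# plane, accepted when the projection stays on the hull
nearest_surface_point <- function(boundary, points) {
  points <- as_points(points)
  V <- boundary$vertices; F <- boundary$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  out <- points
  tol <- 1e-9 * hull_diameter(boundary)
  ex <- cbind(points, -1) %*% rbind(t(boundary$normals), boundary$offsets)
  worst <- max.col(ex, ties.method = "first")
  margin <- ex[cbind(seq_len(nrow(ex)), worst)]
  proj <- points - margin * boundary$normals[worst, , drop = FALSE]
  ok <- hull_margin(boundary, proj) <= tol
  out[ok, ] <- proj[ok, , drop = FALSE]
  for (i in which(!ok)) {
    cand <- closest_on_triangles(points[i, ], A, B, C)
    d2 <- rowSums(sweep(cand, 2, points[i, ])^2)
    out[i, ] <- cand[which.min(d2), ]
  }
  out
}

# inscribed lower-facet approximation of a boundary, from ray-cast surface
# samples on a regular direction grid about the centroid; used where
# per-voxel hull queries dominate (rendering) and ~1% surface error is fine
reduce_boundary <- function(boundary, n_theta = 18, n_phi = 18) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi),
                      cos(g$theta)),
                c(0, 0, -1))
  r <- ray_exit(boundary, boundary$centroid, dirs)
  convex_boundary(sweep(dirs * r, 2, -boundary$centroid))
}

# apply a rigid transform x -> R x + t to a boundary
transform_boundary <- function(boundary, rotation = diag(3), translation = c(0, 0, 0)) {
  b <- boundary
  b$vertices <- sweep(boundary$vertices %*% t(rotation), 2, -translation)
  b$normals <- boundary$normals %*% t(rotation)
  b$offsets <- boundary$offsets + as.numeric(b$normals %*% translation)
  b$centroid <- as.numeric(rotation %*% boundary$centroid + translation)
  b$sampler <- hull_sampler(b)
  b
}
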