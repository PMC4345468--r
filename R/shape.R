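# Ovoid tip detection, orientation, landmark placement and the generalized
# Procrustes mean shape.
#
# Nuclei carry no biologically meaningful landmarks, so correspondence is
# seeded at the "ovoid tip" -- the most pointed end of the nuclear boundary
# in 2D projection (the projection plane is normal to the stack/gravity
# axis, which is shared by all replicates of a study).

# perimeter of a closed 2D polygon clipped to projections along `axis`
# within [t_hi - width, t_hi]
cap_perimeter <- function(poly, axis, t_lo, t_hi) {
  n <- nrow(poly)
  tt <- as.numeric(poly %*% axis)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ta <- tt[i]; tb <- tt[j]
    lo <- min(ta, tb); hi <- max(ta, tb)
    if (hi <= t_lo || lo >= t_hi) next
    # clip segment parameter u in [0,1] to the slab [t_lo, t_hi]
    if (abs(tb - ta) < 1e-15) { u0 <- 0; u1 <- 1 }
    else {
      u0 <- (t_lo - ta) / (tb - ta); u1 <- (t_hi - ta) / (tb - ta)
      if (u0 > u1) { tmp <- u0; u0 <- u1; u1 <- tmp }
      u0 <- max(0, u0); u1 <- min(1, u1)
    }
    if (u1 > u0) tot <- tot + (u1 - u0) * vnorm(b - a)
  }
  tot
}

#' Locate the ovoid tip of a nuclear boundary
#'
#' Hull vertices are projected onto the xy-plane; the principal axis of the
#' 2D convex hull (edge-length-weighted, so vertex density does not bias
#' it) defines two candidate ends. The pointedness of an end is the inverse
#' of the fraction of the 2D hull perimeter falling in the end cap of width
#' 20% of the major-axis extent: a sharper end encloses less perimeter per
#' unit width. Ties (symmetric shapes) break deterministically: larger
#' maximal vertex distance from the 2D centroid, then lexicographic vertex
#' order.
#'
#' @param boundary a `convex_boundary`.
#' @param tip_override optional unit in-plane direction supplied manually
#'   (used when no tip is evident); bypasses detection.
#' @return A list: `direction` (unit 3D vector in the xy-plane), `vertex`
#'   (3D hull vertex extremal along the direction), `pointedness` (the two
#'   candidate scores).
#' @export
find_ovoid_tip <- function(boundary, tip_override = NULL) {
  if (!is.null(tip_override)) {
    d <- c(tip_override[1], tip_override[2], 0)
    if (vnorm(d) == 0) stop("tip_override has zero in-plane length")
    d <- d / vnorm(d)
    proj <- boundary$vertices[, 1:2] %*% d[1:2]
    return(list(direction = d,
                vertex = boundary$vertices[which.max(proj), ],
                pointedness = c(NA_real_, NA_real_)))
  }
  xy <- boundary$vertices[, 1:2, drop = FALSE]
  hull_idx <- grDevices::chull(xy)
  poly <- xy[hull_idx, , drop = FALSE]
  if (nrow(poly) < 3) stop("degenerate 2D projection (collinear vertices)")

  # edge-length-weighted principal axis of the polygon outline
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  mids <- (poly + poly[nxt, , drop = FALSE]) / 2
  lens <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
  ctr <- colSums(mids * lens) / sum(lens)
  cm <- sweep(mids, 2, ctr)
  cov <- t(cm * lens) %*% cm / sum(lens)
  axis <- eigen(cov, symmetric = TRUE)$vectors[, 1]

  tt <- as.numeric(sweep(poly, 2, ctr) %*% axis)
  width <- 0.2 * (max(tt) - min(tt))
  perim <- sum(lens)
  cpoly <- sweep(poly, 2, ctr)
  frac_pos <- cap_perimeter(cpoly, axis, max(tt) - width, Inf) / perim
  frac_neg <- cap_perimeter(cpoly, -axis, max(-tt) - width, Inf) / perim
  point_pos <- 1 / frac_pos
  point_neg <- 1 / frac_neg

  rel_gap <- (point_pos - point_neg) / max(point_pos, point_neg)
  if (abs(rel_gap) > 1e-6) {
    dir2 <- if (rel_gap > 0) axis else -axis
  } else {
    # tie-break 1: larger maximal vertex distance from the 2D centroid
    vd <- rowSums(sweep(poly, 2, ctr)^2)
    dpos <- max(vd[tt >= 0]); dneg <- max(vd[tt <= 0])
    if (abs(dpos - dneg) > 1e-9 * max(dpos, dneg)) {
      dir2 <- if (dpos > dneg) axis else -axis
    } else {
      # tie-break 2: lexicographic order of the extremal vertices
      vpos <- poly[which.max(tt), ]; vneg <- poly[which.min(tt), ]
      dir2 <- if (isTRUE(vpos[1] > vneg[1]) ||
                  (vpos[1] == vneg[1] && vpos[2] >= vneg[2])) axis else -axis
    }
  }
  d <- c(dir2, 0)
  proj <- boundary$vertices[, 1:2] %*% dir2
  list(direction = d, vertex = boundary$vertices[which.max(proj), ],
       pointedness = c(pos = point_pos, neg = point_neg))
}

#' Orient a nucleus by its ovoid tip
#'
#' Rotates about the z axis only (the stack/gravity axis is preserved, and
#' no reflection is ever introduced) so that the tip direction becomes +x,
#' then translates the hull centroid to the origin.
#'
#' @param boundary a `convex_boundary`.
#' @param tip_direction in-plane tip direction from [find_ovoid_tip()].
#' @return A list: `boundary` (oriented), `rotation` (3x3), `translation`
#'   (applied after rotation), so that `oriented = R x + t`.
#' @export
orient_nucleus <- function(boundary, tip_direction) {
  d <- tip_direction
  if (vnorm(d[1:2]) == 0) stop("tip direction has zero in-plane length")
  theta <- atan2(d[2], d[1])
  R <- rot_z(-theta)
  t <- -as.numeric(R %*% boundary$centroid)
  list(boundary = transform_boundary(boundary, R, t), rotation = R,
       translation = t)
}

# apply an orientation (from orient_nucleus) to an n x 3 point matrix
apply_orientation <- function(orientation, points) {
  sweep(as_points(points) %*% t(orientation$rotation), 2, -orientation$translation)
}

#' Place corresponding landmarks on an oriented boundary
#'
#' Landmarks are regular in a spherical parametrization about the origin
#' with the pole axis along +x (the tip): rings at polar angles
#' `j * pi / (n_rings + 1)` and, within each ring, azimuths
#' `2 * pi * k / n_per_ring` measured from +z in the plane normal to +x.
#' Each landmark is the intersection of the ray from the origin with the
#' hull surface. The ordering (tip pole, ring-major azimuth-minor, anti-tip
#' pole) is identical for every replicate, which is what makes the
#' landmarks correspond.
#'
#' @param boundary an oriented `convex_boundary` (tip at +x, centroid at
#'   the origin).
#' @param n_rings number of rings.
#' @param n_per_ring landmarks per ring.
#' @param replicate_id label.
#' @return A `landmark_set`: `landmarks` (L x 3 with
#'   `L = 2 + n_rings * n_per_ring`), `replicate_id`, `rings` / `azimuth`
#'   index vectors.
#' @export
place_landmarks <- function(boundary, n_rings = 9, n_per_ring = 16,
                            replicate_id = "r1") {
  if (hull_margin(boundary, matrix(0, 1, 3)) >= 0)
    stop("origin is not interior to the boundary; orient the nucleus first")
  theta <- seq_len(n_rings) * pi / (n_rings + 1)
  phi <- (seq_len(n_per_ring) - 1) * 2 * pi / n_per_ring
  g <- expand.grid(phi = phi, theta = theta) # ring-major, azimuth-minor
  dirs <- rbind(c(1, 0, 0),
                cbind(cos(g$theta),
                      sin(g$theta) * sin(g$phi),
                      sin(g$theta) * cos(g$phi)),
                c(-1, 0, 0))
  r <- ray_exit(boundary, c(0, 0, 0), dirs)
  structure(list(landmarks = dirs * r, replicate_id = replicate_id,
                 n_rings = n_rings, n_per_ring = n_per_ring,
                 ring = c(0L, rep(seq_len(n_rings), each = n_per_ring),
                          n_rings + 1L),
                 azimuth = c(NA, rep(seq_len(n_per_ring) - 1L, n_rings), NA)),
            class = "landmark_set")
}

# ---- Procrustes machinery -------------------------------------------------

centroid_size <- function(X) sqrt(sum(sweep(X, 2, colMeans(X))^2))

# centre and scale to unit centroid size
procrustes_normalize <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / centroid_size(X)
}

# optimal proper rotation (det +1) aligning X onto Y (Kabsch)
procrustes_rotation <- function(X, Y) {
  s <- svd(t(X) %*% Y)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Full Procrustes distance between two landmark configurations
#'
#' Both configurations are centred and scaled to unit centroid size, then
#' optimally rotated (proper rotations only); the distance is the Frobenius
#' norm of the residual.
#'
#' @param X,Y L x 3 landmark matrices.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(X, Y) {
  Xn <- procrustes_normalize(X)
  Yn <- procrustes_normalize(Y)
  R <- procrustes_rotation(Xn, Yn)
  # optimal scale, then the residual norm computed element-wise (the
  # closed form sqrt(1 - s^2) cancels catastrophically near zero)
  s <- sum((Xn %*% R) * Yn)
  sqrt(sum((s * (Xn %*% R) - Yn)^2))
}

#' Generalized Procrustes analysis mean shape
#'
#' Iterative GPA over the Euclidean similarity transforms: each
#' configuration is centred and scaled to unit centroid size, then
#' repeatedly rotated (proper rotations only) and rescaled in closed form
#' onto the evolving mean; the mean is the landmark-wise average,
#' re-normalized to unit centroid size (the scale constraint). The summed
#' squared distance of the aligned configurations to the mean is
#' non-increasing across iterations.
#'
#' @param landmark_sets list of `landmark_set` objects (>= 2, equal length).
#' @param tol convergence threshold on the mean-shape change (Frobenius
#'   norm).
#' @param max_iter iteration cap.
#' @return A `mean_shape`: `mean_landmarks` (centroid at origin, unit
#'   centroid size), `mean_hull`, `aligned` (list of aligned L x 3
#'   matrices), `per_replicate_residuals` (Procrustes distances to the
#'   mean), `objective_trace`, `converged`, `n_iter`.
#' @export
gpa_mean_shape <- function(landmark_sets, tol = 1e-10, max_iter = 100L) {
  if (length(landmark_sets) < 2) stop("GPA needs at least 2 landmark sets")
  Xs <- lapply(landmark_sets, function(s) {
    if (inherits(s, "landmark_set")) s$landmarks else as_points(s)
  })
  L <- nrow(Xs[[1]])
  if (any(vapply(Xs, nrow, 0L) != L))
    stop("landmark sets have mismatched lengths")
  Xs <- lapply(Xs, procrustes_normalize)
  mean_lm <- Xs[[1]]
  objective <- function(aligned, mu)
    sum(vapply(aligned, function(A) sum((A - mu)^2), 0))
  trace <- numeric(0)
  converged <- FALSE
  aligned <- Xs
  for (it in seq_len(max_iter)) {
    aligned <- lapply(Xs, function(X) {
      R <- procrustes_rotation(X, mean_lm)
      XR <- X %*% R
      b <- sum(XR * mean_lm) # optimal scale (unit-size X, so |X|^2 = 1)
      b * XR
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- procrustes_normalize(new_mean)
    trace <- c(trace, objective(aligned, new_mean))
    delta <- sqrt(sum((new_mean - mean_lm)^2))
    mean_lm <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  res <- vapply(Xs, function(X) procrustes_distance(X, mean_lm), 0)
  structure(list(mean_landmarks = mean_lm,
                 mean_hull = convex_boundary(mean_lm),
                 aligned = aligned,
                 per_replicate_residuals = res,
                 objective_trace = trace,
                 converged = converged, n_iter = length(trace)),
            class = "mean_shape")
}

#' @export
print.mean_shape <- function(x, ...) {
  cat(sprintf("mean_shape: %d landmarks, %d replicates, %s after %d iterations (rms residual %.3g)\n",
              nrow(x$mean_landmarks), length(x$aligned),
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              sqrt(mean(x$per_replicate_residuals^2))))
  invisible(x)
}
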