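# Exact 3D thin-plate-spline registration of each replicate into the mean
# shape, and fusion of all warped compartment centres into the aggregate map.

#' Fit an exact 3D thin-plate spline between corresponding landmarks
#'
#' Solves the standard TPS linear system with the 3D biharmonic kernel
#' `phi(r) = r`: a kernel block, an affine block, and side conditions
#' forcing the kernel weights to sum to zero and be orthogonal to the
#' source coordinates. The fitted map interpolates every landmark exactly
#' (no smoothing); rigid and similarity maps are reproduced with zero
#' kernel weights.
#'
#' @param source L x 3 source landmarks (or a `landmark_set`).
#' @param target L x 3 target landmarks (or a `mean_shape`).
#' @param ridge optional non-negative regularization added to the kernel
#'   diagonal for ill-conditioned cohorts (default 0: exact interpolation).
#' @param replicate_id label used in error messages.
#' @return A `tps_transform`: `source`, `target`, `affine` (4 x 3:
#'   intercept row then linear part) and `weights` (L x 3).
#' @export
fit_tps <- function(source, target, ridge = 0, replicate_id = "r1") {
  S <- if (inherits(source, "landmark_set")) source$landmarks else as_points(source)
  T_ <- if (inherits(target, "mean_shape")) target$mean_landmarks else as_points(target)
  L <- nrow(S)
  if (nrow(T_) != L) stop("source and target landmark counts differ")
  if (L < 5) stop("TPS needs at least 5 landmarks")
  K <- as.matrix(stats::dist(S))
  if (ridge > 0) K <- K + diag(ridge, L)
  P <- cbind(1, S)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(T_, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e)
                    stop(sprintf("replicate %s: singular TPS system (%s)",
                                 replicate_id, conditionMessage(e))))
  # two steps of iterative refinement: the kernel block is moderately
  # ill-conditioned and exact landmark interpolation is the contract
  for (i in 1:2) sol <- sol + solve(A, rhs - A %*% sol)
  structure(list(source = S, target = T_,
                 weights = sol[seq_len(L), , drop = FALSE],
                 affine = sol[L + 1:4, , drop = FALSE]),
            class = "tps_transform")
}

#' Apply a thin-plate-spline transform to points
#'
#' @param tps a `tps_transform`.
#' @param points n x 3 matrix.
#' @return n x 3 matrix of transformed points.
#' @export
tps_apply <- function(tps, points) {
  X <- as_points(points)
  if (nrow(X) == 0) return(X)
  # phi(r) = r kernel against the source landmarks
  d2 <- outer(rowSums(X^2), rowSums(tps$source^2), "+") - 2 * X %*% t(tps$source)
  U <- sqrt(pmax(d2, 0))
  cbind(1, X) %*% tps$affine + U %*% tps$weights
}

#' Warp a point pattern into mean-shape coordinates
#'
#' Points landing outside the mean hull (rare for convex nuclei, since a
#' landmark TPS between convex bodies keeps interiors inside) are clipped
#' to the nearest hull surface point and flagged; the clip rate is a QC
#' metric for deformation artefacts.
#'
#' @param tps a `tps_transform` fitted to the replicate's landmarks.
#' @param pattern a [point_pattern()] in the replicate's (oriented) frame.
#' @param mean_hull the mean shape's `convex_boundary`.
#' @return A [point_pattern()] in mean-shape coordinates with updated
#'   `clipped` flags.
#' @export
warp_points <- function(tps, pattern, mean_hull) {
  W <- tps_apply(tps, pattern$points)
  if (nrow(W) == 0) return(pattern)
  inside <- point_in_hull(mean_hull, W)
  clipped <- !inside
  if (any(clipped))
    W[clipped, ] <- nearest_surface_point(mean_hull, W[clipped, , drop = FALSE])
  point_pattern(W, pattern$replicate_id, source_sizes = pattern$source_sizes,
                clipped = clipped | pattern$clipped)
}

#' Build the aggregate map
#'
#' For each replicate, fits the TPS from its landmarks to the mean
#' landmarks and warps its compartment centres into the mean shape; all
#' warped centres are concatenated with replicate provenance. Replicates
#' with zero compartments still count toward the replicate number R (they
#' carry the information that the expected count is low).
#'
#' @param landmark_sets list of `landmark_set` (one per replicate, in the
#'   same frame as the patterns).
#' @param patterns list of [point_pattern()] (same order).
#' @param mean a `mean_shape` from [gpa_mean_shape()].
#' @param ridge TPS regularization passed to [fit_tps()].
#' @param on_failure `"abort"` (default) or `"skip"` replicates whose TPS
#'   fit fails.
#' @return An `aggregate_map`: `mean` (the mean shape), `points` (fused
#'   n x 3), `replicate_id` (per point), `clipped` (per point), `R`,
#'   `n_i` (named per-replicate counts), `clip_count`, `tps` (the fitted
#'   transforms, cached for the null simulation).
#' @export
build_aggregate_map <- function(landmark_sets, patterns, mean, ridge = 0,
                                on_failure = c("abort", "skip")) {
  on_failure <- match.arg(on_failure)
  if (length(landmark_sets) == 0) stop("no replicates supplied")
  if (length(landmark_sets) != length(patterns))
    stop("landmark_sets and patterns differ in length")
  fused <- list(); ids <- character(0); clipped <- logical(0)
  n_i <- integer(0); tps_list <- list()
  for (i in seq_along(landmark_sets)) {
    id <- landmark_sets[[i]]$replicate_id %||% sprintf("r%03d", i)
    tps <- tryCatch(fit_tps(landmark_sets[[i]], mean, ridge = ridge,
                            replicate_id = id),
                    error = function(e) e)
    if (inherits(tps, "error")) {
      if (on_failure == "abort") stop(conditionMessage(tps))
      warning(sprintf("skipping replicate %s: %s", id, conditionMessage(tps)))
      next
    }
    wp <- warp_points(tps, patterns[[i]], mean$mean_hull)
    fused[[length(fused) + 1]] <- wp$points
    ids <- c(ids, rep(id, nrow(wp$points)))
    clipped <- c(clipped, wp$clipped)
    n_i[id] <- nrow(wp$points)
    tps_list[[id]] <- tps
  }
  if (length(n_i) == 0) stop("no replicate produced a usable TPS fit")
  points <- do.call(rbind, c(fused, list(matrix(numeric(0), 0, 3))))
  structure(list(mean = mean, points = points, replicate_id = ids,
                 clipped = clipped, R = length(n_i), n_i = n_i,
                 clip_count = sum(clipped), tps = tps_list),
            class = "aggregate_map")
}

#' @export
print.aggregate_map <- function(x, ...) {
  cat(sprintf("aggregate_map: %d points from %d replicates (%d clipped)\n",
              nrow(x$points), x$R, x$clip_count))
  invisible(x)
}
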