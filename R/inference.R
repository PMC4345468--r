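# Voxel-wise test of the aggregate map against complete spatial
# randomness, in both the aggregated and dispersed directions, with
# cluster enhancement and Monte-Carlo maximum-statistic calibration.
#
# The key design point: null aggregate maps are built from CSR points drawn
# in each replicate's ORIGINAL boundary and pushed through that replicate's
# already-fitted TPS, so the null distribution carries exactly the same
# nonlinear deformation artefacts as the observed map.

#' Per-voxel intensity excess over (or deficit under) the CSR level
#'
#' @param intensity an `intensity_map`.
#' @param direction `"aggregated"` (intensity above CSR) or `"dispersed"`
#'   (intensity below CSR); negative values are set to zero.
#' @return (z, y, x) array of non-negative excess values, zero outside the
#'   interior.
#' @export
excess_map <- function(intensity, direction = c("aggregated", "dispersed")) {
  direction <- match.arg(direction)
  lam0 <- intensity$csr_level
  ex <- if (direction == "aggregated") intensity$values - lam0
        else lam0 - intensity$values
  ex <- pmax(ex, 0)
  dim(ex) <- intensity$grid$dims
  ex[!intensity$grid$interior_mask] <- 0
  ex
}

#' Cluster-enhance an excess map
#'
#' Default mode `cluster_size`: connected components of strictly positive
#' excess each get a constant statistic equal to the component's volume.
#' Mode `tfce` computes the threshold-free cluster enhancement integral
#' `sum_h e(h, v)^E * h^H * dh` over excess thresholds `h`, where
#' `e(h, v)` is the volume of the component of `{excess >= h}` containing
#' `v` (defaults `E = 0.5`, `H = 2`).
#'
#' @param excess non-negative (z, y, x) array from [excess_map()].
#' @param grid the `voxel_grid`.
#' @param connectivity 6 (default; conservative in 3D), 18 or 26.
#' @param mode `"cluster_size"` or `"tfce"`.
#' @param E,H,dh TFCE exponents and threshold step (`dh = NULL`: 1/50 of
#'   the maximum excess).
#' @param direction label carried through to the result.
#' @return An `enhanced_map`: `grid`, `direction`, `excess`, `statistic`
#'   ((z, y, x) array; volume units in `cluster_size` mode).
#' @export
cluster_enhance <- function(excess, grid, connectivity = 6L,
                            mode = c("cluster_size", "tfce"),
                            E = 0.5, H = 2, dh = NULL,
                            direction = "aggregated") {
  mode <- match.arg(mode)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  vs3 <- grid$voxel_size^3
  stat <- array(0, dim = grid$dims)
  mx <- max(excess)
  if (mx > 0) {
    if (mode == "cluster_size") {
      lab <- label3d_cpp(excess > 0, as.integer(connectivity))
      sizes <- tabulate(lab)
      pos <- lab > 0
      stat[pos] <- sizes[lab[pos]] * vs3
    } else {
      if (is.null(dh)) dh <- mx / 50
      stat <- tfce_cpp(excess, as.integer(connectivity), E, H, dh, vs3)
    }
  }
  structure(list(grid = grid, direction = direction, excess = excess,
                 statistic = stat),
            class = "enhanced_map")
}

# observed enhanced maps in both directions for an aggregate map
observed_enhanced <- function(am, grid, connectivity = 6L,
                              mode = "tfce", E = 0.5, H = 2,
                              dh = NULL, smooth = FALSE) {
  im <- estimate_intensity(am, grid, smooth = smooth)
  list(intensity = im,
       aggregated = cluster_enhance(excess_map(im, "aggregated"), grid,
                                    connectivity, mode, E, H, dh, "aggregated"),
       dispersed = cluster_enhance(excess_map(im, "dispersed"), grid,
                                   connectivity, mode, E, H, dh, "dispersed"))
}

#' Simulate the CSR null distribution of the maximum statistic
#'
#' For each of `M` iterations and each replicate, draws the observed
#' number of points uniformly inside that replicate's own (oriented)
#' boundary, warps them with the replicate's cached TPS transform into the
#' mean shape, fuses them, estimates the intensity on the same grid, and
#' records the maximum cluster-enhanced statistic in each direction. Fully
#' seeded and reproducible.
#'
#' @param am the observed `aggregate_map` (supplies counts `n_i` and the
#'   cached TPS transforms -- transforms are reused, never refitted).
#' @param boundaries named list of each replicate's oriented
#'   `convex_boundary` (the frame the TPS sources live in); names must
#'   cover `names(am$n_i)`.
#' @param grid the `voxel_grid` used for the observed map.
#' @param M number of Monte-Carlo iterations (>= 1).
#' @param seed master seed; iteration i uses `child_seed(seed, i)`.
#' @param connectivity,mode,E,H,dh as in [cluster_enhance()].
#' @param smooth as in [estimate_intensity()].
#' @param keep_stacks also return the per-iteration statistic arrays
#'   (memory-heavy; for diagnostics).
#' @return A `null_samples` list: `max_aggregated`, `max_dispersed`
#'   (length M), `M`, `seed`, and optionally `stacks`.
#' @export
simulate_null <- function(am, boundaries, grid, M = 499L, seed = 1L,
                          connectivity = 6L, mode = "tfce",
                          E = 0.5, H = 2, dh = NULL, smooth = FALSE,
                          keep_stacks = FALSE) {
  if (M < 1) stop("M must be >= 1")
  ids <- names(am$n_i)
  if (!all(ids %in% names(boundaries)))
    stop("boundaries are inconsistent with the aggregate map: missing ",
         paste(setdiff(ids, names(boundaries)), collapse = ", "))
  lam0 <- csr_level(am, grid)
  vs3 <- grid$voxel_size^3
  interior <- grid$interior_mask
  max_a <- numeric(M); max_d <- numeric(M)
  stacks <- if (keep_stacks) vector("list", M) else NULL
  for (m in seq_len(M)) {
    with_seed(child_seed(seed, m), {
      pts <- vector("list", length(ids))
      for (i in seq_along(ids)) {
        id <- ids[i]
        n <- am$n_i[[id]]
        if (n == 0) { pts[[i]] <- matrix(numeric(0), 0, 3); next }
        p0 <- csr_in_hull(boundaries[[id]], n)
        pts[[i]] <- tps_apply(am$tps[[id]], p0)
      }
      fused <- do.call(rbind, pts)
      out <- !point_in_hull(am$mean$mean_hull, fused)
      if (any(out))
        fused[out, ] <- nearest_surface_point(am$mean$mean_hull,
                                              fused[out, , drop = FALSE])
      v <- voronoi_intensity_values(fused, am$R, grid, smooth = smooth)
      for (dir in c("aggregated", "dispersed")) {
        ex <- array(0, dim = grid$dims)
        ex[grid$interior_idx] <- pmax(if (dir == "aggregated") v - lam0
                                      else lam0 - v, 0)
        en <- cluster_enhance(ex, grid, connectivity, mode, E, H, dh, dir)
        if (dir == "aggregated") max_a[m] <- max(en$statistic)
        else max_d[m] <- max(en$statistic)
        if (keep_stacks) stacks[[m]][[dir]] <- en$statistic
      }
    })
  }
  structure(list(max_aggregated = max_a, max_dispersed = max_d, M = M,
                 seed = seed, stacks = stacks),
            class = "null_samples")
}

# Monte-Carlo p-value: (1 + #{null >= s}) / (M + 1), never exactly zero
mc_pvalue <- function(stat, null_max) {
  sorted <- sort(null_max)
  n_lt <- findInterval(stat, sorted, left.open = TRUE) # #{null < s}
  (1 + length(null_max) - n_lt) / (length(null_max) + 1)
}

#' Family-wise significance maps against the CSR null
#'
#' A voxel rejects when its cluster-enhanced statistic exceeds the
#' Monte-Carlo null distribution of the image-wide maximum statistic:
#' `(1 + #{null max >= statistic(v)}) / (M + 1) <= alpha`. Calibrating
#' against the maximum makes this a single hypothesis test on the entire
#' image with family-wise error control.
#'
#' @param observed list with `aggregated` and `dispersed` `enhanced_map`s
#'   (from [observed_enhanced()] or built manually).
#' @param null a `null_samples` object from [simulate_null()].
#' @param alpha level, in (0, 0.5].
#' @return A `significance_map`: `grid`, `reject_aggregated`,
#'   `reject_dispersed` (logical (z, y, x) arrays), per-direction p-value
#'   arrays `p_aggregated` / `p_dispersed`, `alpha`, `n_null`,
#'   `null_max_statistics`.
#' @export
significance_maps <- function(observed, null, alpha = 0.05) {
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  M <- null$M
  if ((M + 1) * alpha < 1)
    stop(sprintf("M = %d null samples cannot resolve alpha = %g; need M >= %d",
                 M, alpha, ceiling(1 / alpha) - 1))
  grid <- observed$aggregated$grid
  out <- list(grid = grid, alpha = alpha, n_null = M,
              null_max_statistics = list(aggregated = null$max_aggregated,
                                         dispersed = null$max_dispersed))
  for (dir in c("aggregated", "dispersed")) {
    en <- observed[[dir]]
    nm <- null[[paste0("max_", dir)]]
    p <- array(mc_pvalue(as.numeric(en$statistic), nm), dim = grid$dims)
    rej <- p <= alpha & grid$interior_mask & en$statistic > 0
    out[[paste0("p_", dir)]] <- p
    out[[paste0("reject_", dir)]] <- rej
  }
  structure(out, class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("significance_map: alpha = %g, %d null samples; %d aggregated / %d dispersed rejecting voxels\n",
              x$alpha, x$n_null, sum(x$reject_aggregated), sum(x$reject_dispersed)))
  invisible(x)
}
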