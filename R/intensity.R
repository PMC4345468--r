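# Voxelization of the mean shape and bandwidth-free intensity estimation.
#
# The estimator is a mass-conserving Voronoi-cell estimator: every interior
# voxel is assigned to its nearest fused point, and a point carrying mass
# 1/R (one centre in one of R replicates) spreads it uniformly over its
# cell. It needs no bandwidth parameter and integrates exactly to the mean
# number of centres per replicate, which makes it directly testable. An
# optional natural-neighbour smoothing pass (inverse-distance weighting
# over points whose Voronoi cells share a face) is available.

#' Voxelize a mean shape
#'
#' Lays an isotropic grid over the mean hull's bounding box with at least
#' one voxel of margin on every side. The voxel edge is chosen so the
#' bounding grid holds about `n_voxels_target` voxels.
#'
#' @param mean a `mean_shape` (or a `convex_boundary`).
#' @param n_voxels_target target number of bounding-grid voxels (default
#'   64^3); values below 100 are rejected as meaninglessly coarse.
#' @return A `voxel_grid`: `origin` (physical (x, y, z) of the grid
#'   corner), `voxel_size`, `dims` (nz, ny, nx), `interior_mask` (z, y, x
#'   logical array over voxel centres), `interior_idx`, `interior_centres`,
#'   `interior_volume`.
#' @export
voxelize <- function(mean, n_voxels_target = 64^3) {
  if (n_voxels_target < 100) stop("n_voxels_target must be at least 100")
  hull <- if (inherits(mean, "mean_shape")) mean$mean_hull else mean
  rng <- apply(hull$vertices, 2, range) # columns x, y, z
  extent <- rng[2, ] - rng[1, ]
  vs <- (prod(extent) / n_voxels_target)^(1 / 3)
  dims_xyz <- ceiling(extent / vs) + 2L # >= 1 voxel margin per side
  origin <- rng[1, ] - (dims_xyz * vs - extent) / 2
  dims <- rev(dims_xyz) # (nz, ny, nx)

  idx <- as.matrix(expand.grid(k = seq_len(dims[1]), j = seq_len(dims[2]),
                               i = seq_len(dims[3])))
  centres <- cbind(origin[1] + (idx[, 3] - 0.5) * vs,
                   origin[2] + (idx[, 2] - 0.5) * vs,
                   origin[3] + (idx[, 1] - 0.5) * vs)
  interior <- logical(nrow(centres))
  chunk <- 65536L
  for (s in seq(1, nrow(centres), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(centres))
    interior[s:e] <- hull_margin(hull, centres[s:e, , drop = FALSE]) <= 0
  }
  mask <- array(interior, dim = dims)
  structure(list(origin = origin, voxel_size = vs, dims = dims,
                 interior_mask = mask,
                 interior_idx = idx[interior, , drop = FALSE],
                 interior_centres = centres[interior, , drop = FALSE],
                 interior_volume = sum(interior) * vs^3),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d (z,y,x), voxel %.4g, %d interior voxels (volume %.4g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              nrow(x$interior_idx), x$interior_volume))
  invisible(x)
}

#' Expected intensity under complete spatial randomness
#'
#' The CSR level is the mean number of centres per replicate divided by the
#' interior volume of the voxelized mean shape.
#'
#' @param am an `aggregate_map`.
#' @param grid a `voxel_grid`.
#' @return Scalar intensity (centres per unit volume per replicate).
#' @export
csr_level <- function(am, grid) {
  if (grid$interior_volume <= 0) stop("voxel grid has zero interior volume")
  (sum(am$n_i) / am$R) / grid$interior_volume
}

# interior intensity values (vector over grid$interior_idx rows) for a fused
# point matrix; the Voronoi-cell estimator with optional natural-neighbour
# smoothing -- shared by the observed and the null simulation paths so both
# see the identical estimator
voronoi_intensity_values <- function(points, R, grid, smooth = FALSE) {
  n_int <- nrow(grid$interior_idx)
  if (nrow(points) == 0) return(numeric(n_int))
  owner <- nearest_point_cpp(grid$interior_centres, points)
  cellvox <- tabulate(owner, nbins = nrow(points))
  val <- ifelse(cellvox > 0, 1 / (R * cellvox * grid$voxel_size^3), 0)
  v <- val[owner]
  # a point whose cell captures no voxel centre (cells smaller than a voxel
  # in crowded regions) deposits its whole mass in its nearest voxel, so
  # the integral stays (sum n_i)/R exactly
  orphan <- which(cellvox == 0)
  if (length(orphan)) {
    vox <- nearest_point_cpp(points[orphan, , drop = FALSE],
                             grid$interior_centres)
    v <- v + tabulate(vox, nbins = n_int) / (R * grid$voxel_size^3)
  }
  if (smooth) v <- nn_smooth(v, owner, val, points, grid)
  v
}

#' Estimate the spatial intensity of an aggregate map
#'
#' @param am an `aggregate_map`.
#' @param grid a `voxel_grid` from [voxelize()].
#' @param smooth apply the natural-neighbour smoothing pass (inverse-
#'   distance-weighted average over the owning point and its Voronoi
#'   face-neighbours, renormalized to preserve total mass). Off by default.
#' @return An `intensity_map`: `grid`, `values` ((z, y, x) array, zero
#'   outside the interior), `csr_level`.
#' @export
estimate_intensity <- function(am, grid, smooth = FALSE) {
  lambda0 <- csr_level(am, grid)
  values <- array(0, dim = grid$dims)
  if (nrow(am$points) == 0) {
    warning("aggregate map contains no points; intensity is uniformly zero")
    return(structure(list(grid = grid, values = values, csr_level = lambda0),
                     class = "intensity_map"))
  }
  values[grid$interior_idx] <- voronoi_intensity_values(am$points, am$R, grid,
                                                        smooth = smooth)
  structure(list(grid = grid, values = values, csr_level = lambda0),
            class = "intensity_map")
}

# natural-neighbour smoothing: voxel value becomes the 1/d-weighted average
# of the cell intensities of the owner and its face-adjacent Voronoi
# neighbours; total mass restored by a single renormalization
nn_smooth <- function(v, owner, lam, points, grid) {
  own_arr <- array(0L, dim = grid$dims)
  own_arr[grid$interior_idx] <- owner
  # face-adjacent voxel pairs with different owners -> natural neighbours
  pairs <- list()
  d <- grid$dims
  for (ax in 1:3) {
    if (ax == 1) { a <- own_arr[-d[1], , , drop = FALSE]; b <- own_arr[-1, , , drop = FALSE] }
    if (ax == 2) { a <- own_arr[, -d[2], , drop = FALSE]; b <- own_arr[, -1, , drop = FALSE] }
    if (ax == 3) { a <- own_arr[, , -d[3], drop = FALSE]; b <- own_arr[, , -1, drop = FALSE] }
    sel <- a > 0 & b > 0 & a != b
    pairs[[ax]] <- cbind(a[sel], b[sel])
  }
  np <- nrow(points)
  pr <- do.call(rbind, pairs)
  a <- pmin(pr[, 1], pr[, 2]); b <- pmax(pr[, 1], pr[, 2])
  key <- unique(a + np * (b - 1))
  a <- ((key - 1) %% np) + 1
  b <- ((key - 1) %/% np) + 1
  nbp <- split(c(b, a, seq_len(np)), c(a, b, seq_len(np))) # neighbours + self
  lens <- lengths(nbp)
  # flatten voxel x candidate-point pairs and do one vectorized IDW pass
  cand_all <- unlist(nbp[owner], use.names = FALSE)
  vox_all <- rep(seq_along(owner), lens[owner])
  d <- sqrt(rowSums((grid$interior_centres[vox_all, , drop = FALSE] -
                       points[cand_all, , drop = FALSE])^2))
  w <- 1 / pmax(d, 1e-9)
  out <- as.numeric(rowsum(w * lam[cand_all], vox_all)) /
    as.numeric(rowsum(w, vox_all))
  mass0 <- sum(v); mass1 <- sum(out)
  if (mass1 > 0) out <- out * (mass0 / mass1)
  out
}

#' @export
print.intensity_map <- function(x, ...) {
  vs3 <- x$grid$voxel_size^3
  cat(sprintf("intensity_map: mass %.4g per replicate, CSR level %.4g\n",
              sum(x$values) * vs3, x$csr_level))
  invisible(x)
}
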