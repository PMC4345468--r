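# ImageStack -> ConvexBoundary + PointPattern of compartment centres.

parse_threshold_method <- function(method) {
  if (is.list(method)) return(method)
  if (identical(method, "otsu")) return(list(method = "otsu"))
  if (grepl("^fixed:", method))
    return(list(method = "fixed", value = as.numeric(sub("^fixed:", "", method))))
  if (grepl("^quantile:", method))
    return(list(method = "quantile", q = as.numeric(sub("^quantile:", "", method))))
  stop("unknown threshold method: ", method)
}

#' Threshold one channel of an image stack
#'
#' Produces a 3D binary mask. Otsu's threshold is computed on the full 3D
#' histogram (not per slice); fixed and quantile thresholds are also
#' available, matching the view that the exact thresholder is
#' interchangeable.
#'
#' @param stack an [image_stack()].
#' @param role channel role (`"envelope"` or `"compartment"`).
#' @param method `"otsu"`, `"fixed:<v>"` or `"quantile:<q>"` (or an
#'   equivalent list).
#' @return A logical (z, y, x) array.
#' @export
threshold_channel <- function(stack, role, method = "otsu") {
  ch <- stack_channel(stack, role)
  m <- parse_threshold_method(method)
  if (all(ch == 0)) {
    warning(sprintf("channel '%s' is all zero; returning an empty mask", role))
    return(array(FALSE, dim = dim(ch)))
  }
  thr <- switch(m$method,
    otsu = {
      top <- max(ch, 255)
      flat <- matrix(ch / top, nrow = dim(ch)[1])
      as.numeric(EBImage::otsu(EBImage::Image(flat), range = c(0, 1),
                               levels = 256)) * top
    },
    fixed = m$value,
    quantile = as.numeric(stats::quantile(ch, m$q, type = 1)),
    stop("unknown threshold method: ", m$method))
  mask <- ch > thr
  dim(mask) <- dim(ch)
  mask
}

# indices (k, j, i) of foreground voxels, reduced to per-(k, j) x-extremes;
# a hull vertex must be extreme along x within its (z, y) row, so this
# reduction loses no hull vertices while shrinking the input dramatically
mask_extreme_voxels <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 1) return(w)
  K <- dim(mask)[1]
  key <- w[, 1] + K * (w[, 2] - 1)
  mn <- tapply(w[, 3], key, min)
  mx <- tapply(w[, 3], key, max)
  keys <- as.numeric(names(mn))
  j <- (keys - 1) %/% K + 1
  k <- keys - K * (j - 1)
  unique(rbind(cbind(k, j, as.numeric(mn)), cbind(k, j, as.numeric(mx))))
}

#' Segment the nuclear boundary as a convex hull
#'
#' The largest 26-connected foreground component of the envelope mask is
#' taken as the nucleus; the convex hull of its voxel centres (in physical
#' units) is the nuclear boundary, justified by the smooth convex shape of
#' fibroblast nuclei.
#'
#' @param mask logical (z, y, x) array from [threshold_channel()].
#' @param spacing physical voxel size (z, y, x).
#' @param replicate_id label used in error messages.
#' @return A `convex_boundary`.
#' @export
boundary_hull <- function(mask, spacing, replicate_id = "r1") {
  lab <- label3d_cpp(mask, 26L)
  sizes <- tabulate(lab)
  if (length(sizes) == 0 || max(sizes) < 4)
    stop(sprintf("replicate %s: fewer than 4 boundary voxels", replicate_id))
  keep <- which.max(sizes)
  sel <- lab == keep
  dim(sel) <- dim(mask)
  idx <- mask_extreme_voxels(sel)
  pts <- voxel_centres(dim(mask), spacing, idx)
  tryCatch(convex_boundary(pts),
           error = function(e)
             stop(sprintf("replicate %s: degenerate boundary (%s)",
                          replicate_id, conditionMessage(e))))
}

#' Extract compartment centres from a binary mask
#'
#' Connected components (26-connectivity by default) with at least
#' `min_size` voxels are each reduced to the unweighted centroid of their
#' voxel centres, in physical units; centroids falling outside the nuclear
#' hull are clipped to the nearest hull surface point and flagged.
#'
#' @param mask logical (z, y, x) array from [threshold_channel()].
#' @param spacing physical voxel size (z, y, x).
#' @param boundary the replicate's `convex_boundary`.
#' @param min_size minimum component size in voxels (rejects single-voxel
#'   noise).
#' @param connectivity 6, 18 or 26.
#' @param replicate_id label attached to the pattern.
#' @return A [point_pattern()] with `source_sizes` and `clipped` flags.
#' @export
compartment_centres <- function(mask, spacing, boundary, min_size = 4L,
                                connectivity = 26L, replicate_id = "r1") {
  lab <- label3d_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  if (length(keep) == 0) return(point_pattern(NULL, replicate_id))
  w <- which(lab > 0, arr.ind = TRUE)
  lw <- lab[lab > 0]
  sel <- lw %in% keep
  w <- w[sel, , drop = FALSE]
  lw <- lw[sel]
  pts <- voxel_centres(dim(mask), spacing, w)
  cent <- rowsum(pts, lw) / as.numeric(table(lw))
  inside <- point_in_hull(boundary, cent,
                          tol = vnorm(spacing) + 1e-9 * hull_diameter(boundary))
  clipped <- !inside
  if (any(clipped))
    cent[clipped, ] <- nearest_surface_point(boundary, cent[clipped, , drop = FALSE])
  point_pattern(cent, replicate_id, source_sizes = sizes[keep],
                clipped = clipped)
}
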