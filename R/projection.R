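# 2D orthogonal-projection summaries of 3D maps, and 3D exports.
#
# The headline visualization: per projection ray, the proportion of
# interior voxels that reject CSR (darkest colour = all voxels along the
# ray reject). The interior voxel count along each ray is kept alongside,
# because near the 2D outline that count is very small and a high
# proportion there can visually overstate the rejecting volume.

# collapse a (z, y, x) array along one axis with a summary over interior
project_collapse <- function(values, interior, axis) {
  ax <- match(axis, c("z", "y", "x"))
  if (is.na(ax)) stop("axis must be one of 'z', 'y', 'x'")
  cnt <- apply(interior, setdiff(1:3, ax), sum)
  tot <- apply(values * interior, setdiff(1:3, ax), sum)
  list(count = cnt, total = tot)
}

#' Project the proportion of rejecting voxels along an axis
#'
#' @param sig a `significance_map`.
#' @param direction `"aggregated"` or `"dispersed"`.
#' @param axis projection axis (default `"z"`, the stack axis).
#' @return A `projection_image`: `pixels` (proportion in `[0, 1]`, `NA`
#'   outside the 2D outline), `count_along_ray`, `axis`, `kind`.
#' @export
project_proportion <- function(sig, direction = c("aggregated", "dispersed"),
                               axis = "z") {
  direction <- match.arg(direction)
  rej <- sig[[paste0("reject_", direction)]]
  pc <- project_collapse(rej, sig$grid$interior_mask, axis)
  px <- ifelse(pc$count > 0, pc$total / pc$count, NA_real_)
  structure(list(pixels = px, count_along_ray = pc$count, axis = axis,
                 kind = "proportion_reject", direction = direction),
            class = "projection_image")
}

#' Project the mean intensity along an axis
#'
#' @param intensity an `intensity_map`.
#' @param axis projection axis (default `"z"`).
#' @return A `projection_image` with `kind = "mean_intensity"`.
#' @export
project_mean_intensity <- function(intensity, axis = "z") {
  pc <- project_collapse(intensity$values, intensity$grid$interior_mask, axis)
  px <- ifelse(pc$count > 0, pc$total / pc$count, NA_real_)
  structure(list(pixels = px, count_along_ray = pc$count, axis = axis,
                 kind = "mean_intensity", direction = NA_character_),
            class = "projection_image")
}

#' Render a projection image to PNG
#'
#' Out-of-domain pixels (no interior voxel along the ray) are drawn in a
#' distinct grey, never as zero.
#'
#' @param proj a `projection_image`.
#' @param path output PNG file.
#' @param n_colours colour resolution.
#' @export
plot_projection <- function(proj, path, n_colours = 64) {
  px <- proj$pixels
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(n_colours, "viridis")
  graphics::par(mar = c(2, 2, 3, 6))
  z <- t(px)[, rev(seq_len(nrow(px))), drop = FALSE]
  rngz <- range(z, na.rm = TRUE)
  if (diff(rngz) == 0) rngz <- rngz + c(0, 1e-12)
  graphics::image(z, col = pal, zlim = rngz, axes = FALSE, useRaster = TRUE,
                  main = sprintf("%s (projection along %s)", proj$kind, proj$axis))
  graphics::mtext("grey = outside domain", side = 1, line = 0.5, cex = 0.8)
  invisible(path)
}

#' Export rejecting voxels and the mean hull for 3D viewing
#'
#' Writes an ASCII PLY point cloud of rejecting voxel centres (optionally
#' with one octant cut away so the centre is visible) and an ASCII PLY
#' triangle mesh of the mean hull.
#'
#' @param sig a `significance_map`.
#' @param mean_hull the mean shape's `convex_boundary`.
#' @param path_prefix output prefix; `_voxels.ply` and `_hull.ply` are
#'   appended.
#' @param direction which rejection map to export.
#' @param cutaway optional octant spec: a vector of three signs in
#'   `{-1, 0, 1}`; voxels with sign-matching coordinates (relative to the
#'   hull centroid) on every non-zero axis are removed.
#' @return Invisibly, a list with the retained voxel-centre matrix and the
#'   written paths.
#' @export
export_3d <- function(sig, mean_hull, path_prefix,
                      direction = c("aggregated", "dispersed"),
                      cutaway = NULL) {
  direction <- match.arg(direction)
  rej <- sig[[paste0("reject_", direction)]]
  idx <- which(rej, arr.ind = TRUE)
  g <- sig$grid
  centres <- cbind(g$origin[1] + (idx[, 3] - 0.5) * g$voxel_size,
                   g$origin[2] + (idx[, 2] - 0.5) * g$voxel_size,
                   g$origin[3] + (idx[, 1] - 0.5) * g$voxel_size)
  if (!is.null(cutaway) && nrow(centres) > 0) {
    rel <- sweep(centres, 2, mean_hull$centroid)
    drop <- rep(TRUE, nrow(centres))
    for (ax in 1:3) if (cutaway[ax] != 0)
      drop <- drop & (sign(rel[, ax]) == cutaway[ax])
    centres <- centres[!drop, , drop = FALSE]
  }
  vox_path <- paste0(path_prefix, "_voxels.ply")
  hull_path <- paste0(path_prefix, "_hull.ply")
  write_ply(vox_path, centres)
  write_ply(hull_path, mean_hull$vertices, mean_hull$faces)
  invisible(list(centres = centres, paths = c(vox_path, hull_path)))
}

# minimal ASCII PLY writer (points, optional triangular faces)
write_ply <- function(path, vertices, faces = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(faces))
    writeLines(c(sprintf("element face %d", nrow(faces)),
                 "property list uchar int vertex_indices"), con)
  writeLines("end_header", con)
  if (nrow(vertices) > 0)
    writeLines(apply(vertices, 1, function(v) paste(v, collapse = " ")), con)
  if (!is.null(faces) && nrow(faces) > 0)
    writeLines(apply(faces - 1L, 1, function(f) paste(c(3L, f), collapse = " ")),
               con)
  invisible(path)
}
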