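# Multi-channel z-stack I/O and tabular/array output.
#
# Axis convention used everywhere: arrays are indexed (z, y, x[, channel]).
# Voxel (k, j, i) (1-based) has physical centre
#   ((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)
# relative to the stack origin, i.e. geometry is done in physical units with
# the voxel-centre convention; anisotropic z-spacing is the norm for
# confocal stacks (~20 slices vs hundreds of pixels laterally).

#' Create an image stack object
#'
#' @param voxels 4D array indexed (z, y, x, channel) of non-negative values.
#' @param spacing physical voxel size along (z, y, x).
#' @param channel_map named integer vector assigning roles to channel
#'   indices; must contain `envelope` and `compartment`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, channel_map) {
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4)
    stop("voxels must be a 4D (z, y, x, channel) array")
  if (any(dim(voxels) == 0)) stop("voxels array has an empty dimension")
  if (is.null(spacing)) {
    warning("no voxel spacing supplied; assuming isotropic 1.0")
    spacing <- c(1, 1, 1)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive (z, y, x) lengths")
  channel_map <- unlist(channel_map)
  for (role in c("envelope", "compartment")) {
    idx <- if (role %in% names(channel_map)) channel_map[[role]] else NULL
    if (is.null(idx) || length(idx) != 1 || is.na(idx))
      stop(sprintf("channel_map must assign role '%s' to exactly one channel", role))
    if (idx < 1 || idx > dim(voxels)[4])
      stop(sprintf("channel_map: role '%s' maps to channel %d but the stack has %d channel(s)",
                   role, idx, dim(voxels)[4]))
  }
  structure(list(voxels = voxels, spacing = setNames(spacing, c("z", "y", "x")),
                 channel_map = channel_map),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d slices of %d x %d pixels, %d channel(s); spacing (z,y,x) = (%g, %g, %g)\n",
              d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# channel of a stack by role, as a 3D (z, y, x) array
stack_channel <- function(stack, role) {
  idx <- if (role %in% names(stack$channel_map)) stack$channel_map[[role]] else NULL
  if (is.null(idx)) stop(sprintf("no channel mapped to role '%s'", role))
  stack$voxels[, , , idx, drop = FALSE][, , , 1]
}

#' Read a multi-page TIFF z-stack
#'
#' Pages are z-slices; channels may be TIFF samples (RGB pages) or absent
#' (single-channel stacks). Pixel values are preserved bit-exactly.
#'
#' @param path a multi-page TIFF file.
#' @param channel_map named integer vector of role -> channel index.
#' @param spacing physical voxel size along (z, y, x); if `NULL`, isotropic
#'   1.0 is assumed with a warning.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map, spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("stack file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # multi-sample pages come back scaled to [0, 1] even under as.is;
  # undo the scaling so integer pixel values survive bit-exactly
  pages <- lapply(pages, function(p) {
    if (is.double(p)) {
      bps <- attr(p, "bits.per.sample") %||% 8L
      p <- round(p * (2^bps - 1))
    }
    p
  })
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("non-uniform page shapes in TIFF: ", paste(unique(shapes), collapse = ", "))
  nz <- length(pages)
  d <- dim(pages[[1]])
  ny <- d[1]; nx <- d[2]; nc <- if (length(d) == 3) d[3] else 1L
  vox <- array(0, dim = c(nz, ny, nx, nc))
  for (k in seq_len(nz)) {
    p <- pages[[k]]
    if (length(dim(p)) == 2) dim(p) <- c(dim(p), 1L)
    vox[k, , , ] <- p
  }
  image_stack(vox, spacing, channel_map)
}

#' Write an image stack as an 8-bit multi-page TIFF
#'
#' @param stack an [image_stack()] with integer values in 0..255.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  v <- stack$voxels
  if (any(v < 0) || any(v > 255)) stop("stack values must lie in 0..255 for 8-bit TIFF")
  pages <- lapply(seq_len(d[1]), function(k) {
    p <- array(v[k, , , ], dim = c(d[2], d[3], d[4]))
    if (d[4] == 1) dim(p) <- d[2:3]
    p / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write keyed records as a headered CSV
#'
#' @param records a data.frame (possibly 0-row).
#' @param path output file.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  read.csv(path)
}

#' Write a voxel map with its grid metadata
#'
#' The array goes into a NIfTI container (with voxel size in the header) and
#' the grid provenance (origin, voxel size, axis order, plus any extra
#' metadata) into a JSON sidecar, so maps reload losslessly.
#'
#' @param values 3D array indexed (z, y, x), finite.
#' @param origin physical (x, y, z) coordinate of the grid corner.
#' @param voxel_size isotropic voxel edge length.
#' @param path output path; `.nii.gz` and `.json` suffixes are added.
#' @param meta optional named list of extra metadata stored in the sidecar.
#' @export
write_array <- function(values, origin, voxel_size, path, meta = list()) {
  if (any(!is.finite(values))) stop("array must be finite")
  img <- RNifti::asNifti(values, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  jsonlite::write_json(
    c(list(origin = as.numeric(origin), voxel_size = voxel_size,
           axis_order = "zyx", dims = dim(values)), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array
#' @export
read_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- array(as.vector(as.array(RNifti::readNifti(paste0(path, ".nii.gz")))),
                  dim = meta$dims)
  list(values = values, origin = meta$origin, voxel_size = meta$voxel_size,
       meta = meta[setdiff(names(meta), c("origin", "voxel_size", "axis_order", "dims"))])
}

# physical (x, y, z) centres of voxels (k, j, i) of a stack
voxel_centres <- function(dims_zyx, spacing_zyx, indices) {
  cbind((indices[, 3] - 0.5) * spacing_zyx[3],
        (indices[, 2] - 0.5) * spacing_zyx[2],
        (indices[, 1] - 0.5) * spacing_zyx[1])
}
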