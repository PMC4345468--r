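# Synthetic cohorts: convex ovoid nuclei, compartment point patterns with
# known spatial preference, and rendered image stacks, so that every
# pipeline stage can be validated against ground truth.

# evaluate `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic nuclear shape
#'
#' Nuclei are modelled as smooth convex ovoids: an ellipsoid with semi-axes
#' `a >= b >= c` (the flattest axis along z, as for fibroblast nuclei lying
#' flat), optional low-frequency radial bumps, and optional sharpening of
#' the +x half that creates a unique "ovoid tip".
#'
#' @param semi_axes three lengths, `a >= b >= c > 0`.
#' @param bump_amplitude radial bump amplitude as a fraction of the local
#'   radius, in `[0, 0.15]` (kept small so the surface stays convex).
#' @param tip_sharpening elongation factor applied to the +x half, in
#'   `[0, 0.5]`; 0 gives an exact ellipsoid.
#' @param seed integer seed for the random bumps, in-plane rotation and
#'   translation.
#' @return A `shape_spec` list.
#' @export
shape_spec <- function(semi_axes, bump_amplitude = 0, tip_sharpening = 0, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(semi_axes <= 0) ||
      semi_axes[1] < semi_axes[2] || semi_axes[2] < semi_axes[3])
    stop("semi_axes must satisfy a >= b >= c > 0")
  if (bump_amplitude < 0 || bump_amplitude > 0.15)
    stop("bump_amplitude must lie in [0, 0.15]")
  if (tip_sharpening < 0 || tip_sharpening > 0.5)
    stop("tip_sharpening must lie in [0, 0.5]")
  structure(list(semi_axes = semi_axes, bump_amplitude = bump_amplitude,
                 tip_sharpening = tip_sharpening, seed = as.integer(seed)),
            class = "shape_spec")
}

# unit directions on a (theta, phi) grid about the +x polar axis, plus poles;
# symmetric under x -> -x and y -> -y so unsharpened shapes project to
# symmetric 2D hulls
ovoid_directions <- function(n_theta = 32, n_phi = 32) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  rbind(c(1, 0, 0),
        cbind(cos(g$theta), sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi)),
        c(-1, 0, 0))
}

#' Generate a synthetic convex nuclear boundary
#'
#' Samples the ovoid surface on a fixed angular grid, verifies convexity
#' post-hoc (every surface sample must lie on the convex hull of the sample
#' set), then applies a random rotation about the z axis and a random
#' in-plane translation (the stack/gravity axis is common to all replicates,
#' emulating cells lying flat).
#'
#' @param spec a [shape_spec()].
#' @param centre nominal (x, y, z) centre of the nucleus before jitter.
#' @param jitter maximum absolute in-plane translation jitter (length units).
#' @return A `convex_boundary` with a `truth` attribute recording the
#'   applied rotation angle, the ground-truth tip direction after rotation,
#'   and the translation.
#' @export
generate_boundary <- function(spec, centre = c(0, 0, 0), jitter = 0) {
  dirs <- ovoid_directions()
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  with_seed(spec$seed, {
    # Build on the unit sphere, where the high curvature keeps small smooth
    # radial bumps convex, then sharpen the +x half and map anisotropically;
    # linear maps preserve convexity exactly.
    r <- rep(1, nrow(dirs))
    if (spec$bump_amplitude > 0) {
      # smooth low-frequency radial modulation from a few random quadric lobes
      u <- matrix(rnorm(9), 3, 3)
      u <- u / sqrt(rowSums(u^2))
      co <- runif(3, -1, 1)
      g <- as.numeric((dirs %*% t(u))^2 %*% co)
      g <- g / max(abs(g), 1e-12)
      r <- r * (1 + spec$bump_amplitude * g)
    }
    pts <- dirs * r
    pts[, 1] <- ifelse(pts[, 1] > 0, pts[, 1] * (1 + spec$tip_sharpening), pts[, 1])
    pts <- pts %*% diag(c(a, b, cc))
    hull <- convex_boundary(pts)
    # post-hoc convexity check: every sample must sit on its own hull
    slack <- hull_margin(hull, pts)
    mean_radius <- mean(sqrt(rowSums(pts^2)))
    if (min(slack) < -1e-3 * mean_radius)
      stop("shape parameters produced a non-convex surface (max inward deviation ",
           signif(-min(slack), 3), ")")
    angle <- runif(1, 0, 2 * pi)
    shift <- c(centre[1] + runif(1, -jitter, jitter),
               centre[2] + runif(1, -jitter, jitter),
               centre[3])
    out <- transform_boundary(hull, rot_z(angle), shift)
    attr(out, "truth") <- list(
      rotation = angle,
      tip_direction = as.numeric(rot_z(angle) %*% c(1, 0, 0)),
      translation = shift, spec = spec)
    out
  })
}

#' Specify a compartment point pattern model
#'
#' @param model one of `csr` (complete spatial randomness), `central`
#'   (aggregation toward the centroid), `annular` (preference for a shell at
#'   a given fractional radius) or `shell_excluded` (CSR with the outer
#'   shell excluded).
#' @param n_points points per nucleus (the mean, when `draw = "poisson"`).
#' @param sigma_r central model: half-normal width of the radial shrinkage
#'   factor (fraction of the original radius).
#' @param r0,w annular model: mean and s.d. of the fractional radius.
#' @param t shell_excluded model: excluded outer shell thickness as a
#'   fraction of the fractional radius.
#' @param draw `"fixed"` or `"poisson"` point-count draw.
#' @param seed integer seed.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(model = c("csr", "central", "annular", "shell_excluded"),
                         n_points = 8, sigma_r = 0.3, r0 = 0.65, w = 0.1,
                         t = 0.2, draw = c("fixed", "poisson"), seed = 1L) {
  model <- match.arg(model)
  draw <- match.arg(draw)
  if (n_points < 0) stop("n_points must be >= 0")
  for (p in c(sigma_r = sigma_r, r0 = r0, w = w, t = t))
    if (p <= 0 || p >= 1) stop("fraction parameters must lie in (0, 1)")
  structure(list(model = model, n_points = n_points, sigma_r = sigma_r,
                 r0 = r0, w = w, t = t, draw = draw, seed = as.integer(seed)),
            class = "pattern_spec")
}

#' Create a point pattern object
#'
#' @param points n x 3 matrix of (x, y, z) compartment centres.
#' @param replicate_id label of the originating replicate.
#' @param source_sizes voxel count of each originating component (NA for
#'   synthetic ground-truth points).
#' @param clipped logical per point: was it clipped to the hull surface.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(points, replicate_id = "r1", source_sizes = NULL,
                          clipped = NULL) {
  points <- if (length(points)) as_points(points) else matrix(numeric(0), 0, 3)
  n <- nrow(points)
  structure(list(points = points, replicate_id = replicate_id,
                 source_sizes = source_sizes %||% rep(NA_integer_, n),
                 clipped = clipped %||% rep(FALSE, n)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern '%s': %d points (%d clipped)\n",
              x$replicate_id, nrow(x$points), sum(x$clipped)))
  invisible(x)
}

#' Sample a compartment point pattern inside a boundary
#'
#' All models place points strictly inside the hull. Radial position is
#' expressed as the fractional radius (distance from the centroid divided by
#' the centroid-to-boundary distance along the same ray), which normalizes
#' away shape variation across nuclei.
#'
#' @param boundary a `convex_boundary`.
#' @param spec a [pattern_spec()].
#' @param replicate_id label attached to the pattern.
#' @return A [point_pattern()].
#' @export
sample_pattern <- function(boundary, spec, replicate_id = "r1") {
  with_seed(spec$seed, {
    n <- if (spec$draw == "poisson") rpois(1, spec$n_points) else spec$n_points
    if (n == 0) return(point_pattern(NULL, replicate_id))
    if (boundary$volume <= 0) stop("cannot sample points in a degenerate boundary")
    ctr <- boundary$centroid
    pts <- switch(spec$model,
      csr = csr_in_hull(boundary, n),
      central = {
        p0 <- csr_in_hull(boundary, n)
        s <- pmin(abs(rnorm(n, 0, spec$sigma_r)), 1)
        sweep(sweep(p0, 2, ctr) * s, 2, -ctr)
      },
      annular = {
        dirs <- matrix(rnorm(3 * n), n, 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        f <- pmin(pmax(rnorm(n, spec$r0, spec$w), 1e-6), 1 - 1e-6)
        sweep(dirs * (f * ray_exit(boundary, ctr, dirs)), 2, -ctr)
      },
      shell_excluded = {
        out <- matrix(numeric(0), 0, 3)
        while (nrow(out) < n) {
          cand <- csr_in_hull(boundary, 2 * (n - nrow(out)) + 8)
          keep <- fractional_radius(boundary, cand) <= 1 - spec$t
          out <- rbind(out, cand[keep, , drop = FALSE])
        }
        out[seq_len(n), , drop = FALSE]
      })
    point_pattern(pts, replicate_id)
  })
}

#' Default imaging parameters for synthetic rendering
#'
#' Emulates a confocal stack of ~20 z-slices with anisotropic spacing:
#' the envelope channel is a stained shell around the hull surface, the
#' compartment channel a set of spherical blobs, both blurred and corrupted
#' with Poisson-like noise and quantized to 8 bits.
#'
#' @param dims stack dimensions (nz, ny, nx).
#' @param spacing voxel size (z, y, x) in length units.
#' @param envelope_thickness full thickness of the envelope shell.
#' @param blob_radius radius of a rendered compartment blob.
#' @param blur_sigma Gaussian blur s.d. in physical units, per (z, y, x)
#'   axis (a scalar is used isotropically; 0 disables). The default axial
#'   s.d. is larger than the lateral one, as for a confocal point-spread
#'   function.
#' @param noise Poisson-like noise scale (0 disables; larger is noisier).
#' @param seed integer seed for the noise.
#' @return A named list of imaging parameters.
#' @export
imaging_params <- function(dims = c(20, 250, 250), spacing = c(0.5, 0.1, 0.1),
                           envelope_thickness = 0.4, blob_radius = 0.4,
                           blur_sigma = c(0.35, 0.15, 0.15), noise = 0.5,
                           seed = 1L) {
  if (length(blur_sigma) == 1) blur_sigma <- rep(blur_sigma, 3)
  list(dims = as.integer(dims), spacing = as.numeric(spacing),
       envelope_thickness = envelope_thickness, blob_radius = blob_radius,
       blur_sigma = as.numeric(blur_sigma), noise = noise,
       seed = as.integer(seed))
}

# separable 3D gaussian blur, sigma given per (z, y, x) axis in voxels
gauss_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  blur_axis <- function(a, axis, sg) {
    if (sg <= 0) return(a)
    half <- max(1L, ceiling(3 * sg))
    k <- dnorm(seq(-half, half), sd = sg)
    k <- k / sum(k)
    n <- d[axis]
    # band matrix applying 1D convolution with edge renormalization
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      idx <- seq_len(n)
      tgt <- idx + o
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[o + half + 1]
    }
    K <- K / rowSums(K)
    m <- apply(a, setdiff(1:3, axis), function(v) as.numeric(K %*% v))
    aperm(m, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma_vox[ax])
  arr
}

#' Render a synthetic nucleus as an 8-bit image stack
#'
#' @param boundary a `convex_boundary` (physical coordinates must fit the
#'   stack extent `dims * spacing`).
#' @param pattern a [point_pattern()] of compartment centres.
#' @param imaging an [imaging_params()] list.
#' @return An [image_stack()] with channels `envelope` = 1, `compartment` = 2.
#' @export
render_stack <- function(boundary, pattern, imaging = imaging_params()) {
  dims <- imaging$dims; sp <- imaging$spacing
  extent <- rev(dims * sp) # (x, y, z)
  rngv <- apply(boundary$vertices, 2, range)
  over <- c("x", "y", "z")[rngv[1, ] < 0 | rngv[2, ] > extent]
  if (length(over))
    stop("boundary exceeds the stack extent along axis/axes: ",
         paste(over, collapse = ", "))

  # envelope shell painted on the interior face of the boundary (lamin lines
  # the inner nuclear membrane), so the stain's outer edge is the true
  # surface. The facet-plane margin is the (near-surface exact) signed
  # distance and is 1-Lipschitz in position, so a coarse-grid pass bounds it
  # rigorously and only voxels near the shell need the exact facet sweep.
  env <- array(0, dim = dims)
  f <- 4L
  cdims <- pmax(1L, ceiling(dims / f))
  cidx <- as.matrix(expand.grid(k = seq_len(cdims[1]), j = seq_len(cdims[2]),
                                i = seq_len(cdims[3])))
  csp <- sp * f
  ccen <- cbind((cidx[, 3] - 0.5) * csp[3], (cidx[, 2] - 0.5) * csp[2],
                (cidx[, 1] - 0.5) * csp[1])
  reach <- 0.5 * sqrt(sum(csp^2)) # max offset of a fine voxel centre
  cm <- hull_margin(boundary, ccen)
  cand <- which(cm >= -imaging$envelope_thickness - reach & cm <= reach)
  if (length(cand)) {
    fine <- vector("list", length(cand))
    for (ci in seq_along(cand)) {
      cc <- cidx[cand[ci], ]
      fine[[ci]] <- as.matrix(expand.grid(
        k = ((cc[1] - 1) * f + 1):min(cc[1] * f, dims[1]),
        j = ((cc[2] - 1) * f + 1):min(cc[2] * f, dims[2]),
        i = ((cc[3] - 1) * f + 1):min(cc[3] * f, dims[3])))
    }
    fine <- do.call(rbind, fine)
    fcen <- voxel_centres(dims, sp, fine)
    m <- hull_margin(boundary, fcen)
    sel <- m <= 0 & m >= -imaging$envelope_thickness
    env[fine[sel, , drop = FALSE]] <- 200
  }

  comp <- array(0, dim = dims)
  if (nrow(pattern$points) > 0) {
    for (p in seq_len(nrow(pattern$points))) {
      pt <- pattern$points[p, ]
      lo <- pmax(1L, floor(c((pt[3] - imaging$blob_radius) / sp[1],
                             (pt[2] - imaging$blob_radius) / sp[2],
                             (pt[1] - imaging$blob_radius) / sp[3])) + 1L)
      hi <- pmin(dims, ceiling(c((pt[3] + imaging$blob_radius) / sp[1],
                                 (pt[2] + imaging$blob_radius) / sp[2],
                                 (pt[1] + imaging$blob_radius) / sp[3])))
      if (any(lo > hi)) next
      sub <- as.matrix(expand.grid(k = lo[1]:hi[1], j = lo[2]:hi[2], i = lo[3]:hi[3]))
      cc <- voxel_centres(dims, sp, sub)
      d2 <- rowSums(sweep(cc, 2, pt)^2)
      inside <- sub[d2 <= imaging$blob_radius^2, , drop = FALSE]
      if (nrow(inside)) comp[inside] <- 255
    }
  }

  bs <- imaging$blur_sigma
  if (length(bs) == 1) bs <- rep(bs, 3)
  if (any(bs > 0)) {
    sv <- bs / sp
    env <- gauss_blur3(env, sv)
    comp <- gauss_blur3(comp, sv)
  }
  if (imaging$noise > 0) {
    with_seed(imaging$seed, {
      env <- rpois(length(env), pmax(env, 0) / imaging$noise) * imaging$noise
      comp <- rpois(length(comp), pmax(comp, 0) / imaging$noise) * imaging$noise
      dim(env) <- dims; dim(comp) <- dims
    })
  }
  vox <- array(0, dim = c(dims, 2))
  vox[, , , 1] <- pmin(pmax(round(env), 0), 255)
  vox[, , , 2] <- pmin(pmax(round(comp), 0), 255)
  image_stack(vox, sp, c(envelope = 1, compartment = 2))
}

#' Generate a synthetic cohort of nuclei
#'
#' Per-nucleus shape parameters are drawn independently (semi-axes jittered
#' around the template), each nucleus gets its own rotation, translation and
#' point pattern, and (optionally) a rendered image stack. Ground truth is
#' retained for end-to-end validation.
#'
#' @param n_nuclei number of replicate nuclei (>= 1).
#' @param shape template [shape_spec()]; per-nucleus semi-axes are jittered
#'   by `axis_jitter` (relative s.d., truncated at +/- 2 s.d.).
#' @param pattern template [pattern_spec()].
#' @param imaging an [imaging_params()] list (used when `render = TRUE`).
#' @param seed master seed; per-nucleus seeds derive from it via
#'   [child_seed()].
#' @param axis_jitter relative s.d. of the semi-axis jitter.
#' @param render render image stacks (slower); if `FALSE` only ground-truth
#'   boundaries and patterns are returned.
#' @return A list with class `synthetic_cohort`: one element per nucleus,
#'   each a list with `stack` (or `NULL`), `boundary`, `pattern`,
#'   `replicate_id`.
#' @export
generate_cohort <- function(n_nuclei, shape = shape_spec(c(7, 5.5, 2.2), 0.05, 0.3),
                            pattern = pattern_spec("csr", 8),
                            imaging = imaging_params(), seed = 1L,
                            axis_jitter = 0.1, render = FALSE) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  extent <- rev(imaging$dims * imaging$spacing)
  centre <- extent / 2
  lapply_out <- lapply(seq_len(n_nuclei), function(i) {
    sseed <- child_seed(seed, 2L * i)
    pseed <- child_seed(seed, 2L * i + 1L)
    axes <- with_seed(child_seed(seed, 1000000L + i), {
      j <- pmin(pmax(rnorm(3, 0, axis_jitter), -2 * axis_jitter), 2 * axis_jitter)
      sort(shape$semi_axes * (1 + j), decreasing = TRUE)
    })
    sspec <- shape_spec(axes, shape$bump_amplitude, shape$tip_sharpening, sseed)
    jitter <- if (render) 0.02 * min(extent[1:2]) else 0
    bnd <- generate_boundary(sspec, centre = if (render) centre else c(0, 0, centre[3]),
                             jitter = jitter)
    pspec <- pattern
    pspec$seed <- pseed
    pat <- sample_pattern(bnd, pspec, replicate_id = sprintf("r%03d", i))
    stk <- if (render) {
      img <- imaging
      img$seed <- child_seed(seed, 3000000L + i)
      render_stack(bnd, pat, img)
    } else NULL
    list(stack = stk, boundary = bnd, pattern = pat,
         replicate_id = sprintf("r%03d", i))
  })
  structure(lapply_out, class = "synthetic_cohort",
            seed = seed, model = pattern$model)
}
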