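---
title: "Aggregate maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Point-like nuclear compartments — PML nuclear bodies, RNA polymerase II
foci, splicing speckles — occupy positions inside the nucleus that may be
spatially structured, but any single nucleus carries too few compartments
(often fewer than ten) to reveal that structure, and nuclei vary in both
size and shape, so their point patterns cannot simply be overlaid. An
*aggregate map* solves this by building an average nuclear shape from many
replicate nuclei, warping every replicate's compartment centres into that
average shape, and then asking, voxel by voxel, whether the fused pattern
is denser (aggregated) or sparser (dispersed) than complete spatial
randomness (CSR) would allow.

`nucleomap` implements that whole chain: segmentation of 3D confocal
stacks, convex-hull boundary extraction, landmark placement seeded at the
ovoid tip, a generalized Procrustes (GPA) mean shape, exact 3D thin-plate
spline (TPS) registration, a bandwidth-free spatial intensity estimator,
and a cluster-enhanced Monte-Carlo test against CSR, with 2D orthogonal
projections of the result. A synthetic-cohort generator with known
spatial-preference models provides ground truth for every stage.

## Pipeline and model

### Segmentation

The envelope (lamin B) channel is thresholded — Otsu's method on the full
3D histogram by default; the method is pluggable because nothing
downstream depends on the specific thresholder — and the largest
26-connected component's voxel centres, in physical units, are reduced to
their convex hull. Convexity is a modelling decision justified by the
smooth, convex shape of fibroblast nuclei; it buys exact and fast
point-in-body, ray-casting and uniform-sampling primitives. The
compartment channel is thresholded the same way; each connected component
with at least `min_size` voxels (default 4, rejecting single-voxel noise)
becomes the unweighted centroid of its voxel centres. Binary rather than
intensity-weighted centroids are the default because they are stable
under threshold changes.

All geometry uses the voxel-centre convention: voxel `(k, j, i)` sits at
`((i-0.5)*sx, (j-0.5)*sy, (k-0.5)*sz)`. Confocal stacks are strongly
anisotropic (here ~20 slices against 250×250 pixels), so index-space
geometry would be wrong; physical spacing is attached to every stack and
defaults to isotropic 1.0 with a warning when unknown.

### Orientation and landmarks

Nuclei have no biologically meaningful landmarks, so correspondence is
manufactured geometrically. Each hull is projected onto the xy-plane (the
stack axis, shared by all replicates because the cells lie flat under
gravity, is never mixed into the projection). The principal axis of the
2D outline — edge-length weighted, so vertex density cannot bias it —
gives two candidate ends; the *ovoid tip* is the end whose cap (20% of
the major-axis extent) contains the smaller fraction of the outline
perimeter, i.e. the more pointed end. Exactly symmetric shapes fall back
to deterministic tie-breaks (larger maximal vertex distance from the 2D
centroid, then lexicographic order), and a per-replicate manual override
exists for nuclei without an evident tip. The nucleus is then rotated
about z so the tip points along +x and translated so the hull centroid is
at the origin. Rotations are proper and z-only: gravity orientation is a
physical invariant of the data, and reflections would be meaningless.

Landmarks are placed by ray-casting from the centroid on a regular
spherical parametrization about the +x pole: `n_rings` polar rings
(default 9) of `n_per_ring` azimuths (default 16) plus the two poles,
L = 146. "Regularly spaced" is implemented as regular in solid angle, not
geodesic arc length: on convex bodies this gives exact cross-replicate
correspondence with no optimization, which is the property GPA and TPS
actually need. The landmark count needs no fine tuning for such simple
shapes; it is exposed in the configuration regardless.

### Mean shape (GPA)

Configurations are centred, scaled to unit centroid size, and iteratively
rotated (Kabsch, constrained to determinant +1) and rescaled in closed
form onto the evolving mean, which is re-normalized to unit size each
iteration — the standard full-GPA scale constraint. The summed squared
distance to the mean is recorded per iteration and asserted
non-increasing in the tests; convergence is declared when the mean moves
less than `1e-10` (Frobenius).

### Registration and fusion (TPS)

Each replicate's landmarks are mapped onto the mean landmarks by an exact
3D thin-plate spline with kernel `phi(r) = r`, the biharmonic fundamental
solution in 3D (the 2D `r^2 log r` kernel would be wrong here). No
smoothing is applied — landmark correspondence is exact by construction —
though a ridge term exists in the configuration for numerically
degenerate cohorts. The side conditions (kernel weights summing to zero
and orthogonal to the source coordinates) are part of the linear system
and are asserted in tests; affine maps are reproduced with zero kernel
weights to machine precision.

Compartment centres are pushed through their replicate's TPS and fused.
A warped point can land slightly outside the mean hull: the mean shape is
a 146-vertex polytope, and points lying in the sagitta gap between the
true smooth boundary and an inscribed facet (up to ~2% of the radius at
the default landmark density) warp to just outside the corresponding
mean facet. Such points are clipped to the nearest hull surface point,
flagged, and counted (the clip rate is a QC metric in the run manifest;
a few percent is geometry, not error). Crucially, the null simulation
treats its points identically, so the test stays calibrated. Replicates
with zero compartments still count toward the replicate number R: the
intensity is "expected centres per replicate per unit volume", and an
empty replicate is evidence that this expectation is small.

### Intensity estimation

The mean hull is voxelized on an isotropic grid (default: the bounding
box divided into about 64^3 voxels; interior = voxel centres inside the
hull). The published estimator for this methodology is a
natural-neighbour scheme whose precise algorithm is not public; this
package implements a mass-conserving Voronoi-cell estimator in its
place and documents it as such. Every interior voxel is assigned to its
nearest fused point (ties to the lowest point index, so the map is
deterministic); a point carrying mass 1/R spreads it uniformly over its
cell, giving intensity `1/(R * V_cell)`. In crowded regions a cell can be
smaller than a voxel and capture no voxel centre; such a point deposits
its whole mass in its nearest interior voxel instead, so the integral is
preserved for concentrated patterns too. The estimator shares the two
properties that motivated the original: it needs no bandwidth parameter,
and it integrates exactly to the observed mean count per replicate
(`sum(values) * voxel^3 = sum(n_i)/R`), which makes it directly testable.

An optional *natural-neighbour smoothing pass* replaces each voxel's
value with the inverse-distance-weighted average over the owning point
and its Voronoi face-neighbours, then renormalizes to preserve mass. It
is off by default (the raw estimator is the simpler object and is what
the mass-conservation and ownership oracles pin down), but it matters
for one class of patterns: boundary-deficit alternatives. Without
smoothing, the huge Voronoi cells of the outermost points extend deep
into the interior, so a boundary exclusion zone smears inward and
dispersed-direction rejections are not spatially confined to the
boundary shell; with smoothing they are. Conversely, smoothing flattens
sharp interior peaks, which is exactly what the height-weighted TFCE
statistic rewards, so it costs power against central aggregation. The
validation studies therefore use the smoothed estimator for the
boundary-deficit (shell-excluded) alternative and the raw estimator
elsewhere; the null simulation always uses the identical estimator
settings as the observed map, so calibration is unaffected either way.

### Inference

Per voxel, the excess over CSR is `max(intensity - lambda0, 0)` in the
aggregated direction and `max(lambda0 - intensity, 0)` in the dispersed
direction, with `lambda0 = (sum(n_i)/R) / interior_volume`. The excess is
then cluster-enhanced. Two statistics are implemented:

* `cluster_size`: each connected component of strictly positive excess
  gets its volume as the statistic. This is what the methodology's
  figures display, and it is kept as the visualization mode — but it has
  essentially no power as a test statistic with realistic point counts,
  because roughly half of all Voronoi cells exceed `lambda0` under CSR
  and the supra-zero set percolates into one giant component in null and
  signal maps alike.
* `tfce` (default for inference): threshold-free cluster enhancement,
  `sum_h e(h,v)^E * h^H * dh` over thresholds `h` up to the maximum
  excess (E = 0.5, H = 2, 50 thresholds), computed incrementally with a
  union-find over descending thresholds. Weighting cluster height as
  well as extent is precisely what separates a genuine intensity peak
  from a percolating near-zero fluctuation, and TFCE is the approach the
  methodology names for this step.

The null distribution is the heart of the design: for each of M
iterations (default 499), CSR points are drawn *in each replicate's own
oriented boundary* with the observed counts `n_i`, pushed through that
replicate's *already-fitted* TPS (cached, never refitted), fused,
estimated and enhanced identically to the observed data. Null aggregate
maps therefore carry exactly the same nonlinear deformation artefacts as
the observed one, which neutralizes registration artefacts by
construction. A voxel rejects when
`(1 + #{null max statistic >= statistic(v)}) / (M + 1) <= alpha`
(never exactly zero); calibrating against the null *maximum* makes the
procedure a single test on the entire image with family-wise error
control, and the rejection rule is monotone in the statistic by
construction. M must satisfy `(M+1) * alpha >= 1` or no rejection is
possible; per-voxel uncorrected p-values are also returned but are
exploratory.

Uniform sampling inside a hull is exact, not rejection-based: a
tetrahedron of the centroid fan is chosen with probability proportional
to volume and a point drawn by cube-to-simplex folding. This consumes a
fixed number of random draws per point, which keeps the counter-based
seed scheme (`child_seed(master, iteration)`) exactly reproducible.

### Projections

Maps are summarized as 2D orthogonal projections along the stack axis:
per projection ray, the proportion of interior voxels that reject (or
the mean intensity). Rays with no interior voxels are `NA` — rendered
distinctly, never as zero — and the interior voxel count per ray is
returned alongside, because near the 2D outline that count is small and
a high proportion there can visually overstate the rejecting volume.
Rejecting voxels and the mean hull also export to ASCII PLY, optionally
with an octant cut away so the centre of the map is visible.

## The synthetic-data generator

The generator is the package's ground truth and defines its study
conditions. Nuclei are smooth convex ovoids: a unit sphere with optional
low-frequency radial bumps (amplitude <= 0.15 of the radius; applied on
the sphere, where curvature keeps small smooth bumps convex), an optional
sharpening of the +x half (factor `1 + tip_sharpening`), then anisotropic
scaling to semi-axes a >= b >= c — linear maps preserve convexity
exactly, and a post-hoc check errors out if sampling still produced a
non-convex surface. Template semi-axes are (7, 5.5, 2.2) length units (a ~14 x 11 x 4.4
micron nucleus, which fits a 25-micron field of view with margin even
after sharpening and jitter) with 10% i.i.d. relative jitter, bump
amplitude 0.05 and sharpening 0.3, emulating flat-lying fibroblast
nuclei with a recognizable ovoid tip;
each nucleus gets a random rotation about z (the gravity axis is common
to all replicates, so only in-plane rotation is realistic) and an
in-plane translation.

Compartment patterns use the *fractional radius* (distance from the
centroid over centroid-to-boundary distance along the same ray) as their
shape-normalized radial coordinate — the same normalization the
aggregate map itself performs, which is what makes ground truth
comparable across differently shaped nuclei. Four models: `csr`;
`central` (radial shrinkage by a |N(0, sigma_r)| factor, default
sigma_r = 0.3); `annular` (fractional radius ~ N(r0 = 0.65, w = 0.1)
along uniform directions); and `shell_excluded` (CSR conditioned on
fractional radius <= 1 - t, default t = 0.2). Rendering paints an
envelope shell (thickness 0.4) and spherical compartment blobs (radius
0.4 — large enough that a blob can never fall entirely between two
z-slices at the 0.5 z-step) into a 20 x 250 x 250 stack at
(0.5, 0.1, 0.1) spacing, blurs with
a separable anisotropic Gaussian (s.d. 0.35 axially, 0.15 laterally, as
for a confocal point-spread function -- the axial blur also keeps the
thin envelope shell connected across 0.5-step z-slices), adds
Poisson-like noise and quantizes to 8 bits.

What the generator does *not* emulate: chromatin texture, nucleoli,
non-convex or mitotic nuclei, anisotropic PSFs, uneven illumination, or
touching compartments. Passing tests therefore demonstrate that the
statistical machinery recovers known spatial preferences under the
stated geometry and imaging model — not that segmentation is robust to
every real-world artefact.

## Validation studies and problem sizes

The package validates itself with simulation studies run by the test
suite and the acceptance script:

* *Type-I error*: cohorts of R = 20 nuclei with ~8 CSR points each,
  M = 199 nulls, alpha = 0.05, 32^3 grid; the fraction of cohorts with
  any rejection is compared against alpha plus twice its binomial
  standard error. The suite runs 60 such cohorts (the reference
  experiment envisages 200; 60 keeps the default test run to a few
  minutes on one CPU and still detects gross miscalibration — the
  acceptance band widens accordingly via the same binomial formula).
* *Power and localization*: cohorts of R = 50 nuclei, 10 points each,
  M = 199, 24^3 grid (smoothed estimator for the shell-excluded
  alternative, raw otherwise), 12 cohorts per alternative:
  central cohorts must place the volume-weighted centroid of aggregated
  rejections within 0.15 hull radii of the centre; shell-excluded
  cohorts must confine dispersed rejections to fractional radius > 0.6;
  annular cohorts must put the median fractional radius of aggregated
  rejections in (0.4, 0.9). Each must hold in >= 90% of cohorts.
* *Segmentation fidelity*: blur- and noise-free renders of three nuclei
  (semi-axes around 6 x 5 x 3) at 0.25 um z-steps and 0.1 um lateral
  pixels, with compartments thinned to at least four blob radii of
  separation (touching compartments are out of scope). Counts must be
  exact, centroids within one voxel diagonal, hull volume within 5%.
  The fine z-step matters: the hull of voxel *centres* loses up to half
  a voxel per face, which alone is ~10% of the volume of a 6-um-tall
  nucleus at 0.5-um steps — a sampling property of the boundary
  estimator worth knowing when imaging real cells, and the reason the
  fidelity study is run at finer z than a typical 20-slice stack.
* The shell-excluded study is the hardest of the three and sits at the
  edge of its target: across repeated cohorts the joint requirement
  (dispersed rejections present and all of them beyond fractional radius
  0.6) holds in roughly 85-90% of cohorts, with occasional cohorts
  producing no boundary rejection at all. That is not an implementation
  artefact but the method's reduced power near the boundary, see below.
* Reduced power near the boundary is expected and real: interior voxels
  outnumber boundary voxels along most projection rays, boundary voxels
  sit in fewer, larger Voronoi cells, and clipping piles both observed
  and null points onto the surface. The shell-excluded study passes
  despite this because the deficit there is total, not marginal.

Numerical conventions worth knowing: Voronoi ownership ties go to the
lowest point index; TFCE uses 50 thresholds of the per-map maximum
(`dh = max/50`), so maps with different maxima use different Riemann
steps of the same integral; the GPA objective is asserted non-increasing
to 1e-9 slack; convex hulls treat points within 1e-9 of a facet plane
(relative to the diagonal) as interior, and containment tests carry the
matching tolerance; degenerate inputs (coplanar masks, zero-volume
hulls, empty patterns, all-zero channels) either error with the
replicate named or produce the documented empty result, never silence.

## Known limitations

* The boundary model is a convex polytope; lobed or indented nuclei
  violate it silently (the hull just bridges the indentation).
* The intensity estimator is a stand-in for the unpublished
  natural-neighbour scheme; it shares its stated design goals
  (bandwidth-free, intensity-interpretable, mass-conserving) but not
  necessarily its exact values.
* The ovoid-tip rule is this package's operationalization of "most
  pointed end in 2D projection"; it is deterministic,
  rotation-equivariant and validated on synthetic ground truth (within
  15 degrees at sharpening >= 0.2), but near-circular projections are
  resolved by tie-breaks or manual override, not by evidence.
* Warping moves points, not voxel images; extended compartments
  (nucleoli, speckles treated as regions) are out of scope.
* The Monte-Carlo test controls family-wise error against the null
  maximum; it does not produce per-voxel adjusted p-values with
  voxel-level guarantees.
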