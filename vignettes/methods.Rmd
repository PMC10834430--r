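---
title: "From binary bone segmentations to FE-ready models: methods and design"
author: "bonessm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binary bone segmentations to FE-ready models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automatic knee-MRI segmentation networks produce voxel masks of the femur
and tibia that are accurate in the Dice sense but geometrically coarse:
staircase topology, speckle, occasional holes. Surfaces extracted directly
from such masks are poor starting points for finite-element (FE) meshing.
`bonessm` implements the classical remedy: build a statistical shape model
(SSM) of the bone from a training population, then *adjust* each new
segmentation by fitting the model to its surface. The fitted surface is
smooth, hole-free and anatomically plausible by construction, at the cost
of living inside the model's span. Downstream, the package selects the
bone–cartilage contact patch, extrudes a layered hexahedral cartilage mesh
with nodes shared at the bone interface, and exports an Abaqus INP deck.
Finally, time-varying mechanical outputs of two model variants can be
compared over the stance phase with one-dimensional statistical parametric
mapping (SPM).

## The shape model

The model is the linear point-distribution model

$$\mathrm{Shape} = M + \mathrm{PC}\,b,$$

with `M` the mean of `K` corresponded surface points, `PC` orthonormal
principal components of the mean-centred training sets, and `b` the
per-mode weights. Everything hinges on correspondence quality; the pipeline
is:

1. **Template preparation.** One training surface is remeshed to a uniform
   vertex budget (`remesh_template()`: voxelize, re-extract, project back
   to the input, tangential relaxation) and smoothed with the Taubin
   lambda/mu scheme, which does not shrink the surface the way plain
   Laplacian smoothing does.
2. **Point sampling.** Poisson-disk sampling draws well-separated surface
   points (greedy acceptance from an oversampled pool with a shrinking
   radius; the accepted minimum distance never falls below 0.55 of the
   ideal hexagonal-packing radius), followed by a uniformization relaxation
   that pushes each point away from its nearest neighbour when closer than
   the median spacing and reprojects onto the surface. Iterations that
   would increase the spread of nearest-neighbour distances are rejected.
3. **Coarse alignment** of each sample to the template by centroid,
   centroid size and principal axes. Axis-sign ambiguity is resolved by
   matching third moments; reflections are forbidden. This step is where
   anatomical asymmetry matters: a perfectly symmetric shape would make the
   sign choice arbitrary.
4. **Coherent point drift (CPD).** Rigid/similarity CPD aligns the template
   points to the sample cloud, then non-rigid CPD (`v = G W`, Gaussian
   kernel width `beta = 2` and coherence weight `lam = 3` in unit-RMS
   coordinates, outlier weight `w = 0.1`) deforms them onto it. The CPD
   target cloud is sampled three times denser than the template
   (`n_target_points = 3 * n_points`): the E-step is linear in the target
   size while the M-step solve is cubic in the template size, so dense
   targets buy a large reduction of the Gaussian-mixture sampling noise at
   almost no cost.
5. **Projection and smoothing.** Each deformed template point is projected
   to its closest point on the sample surface; the resulting displacement
   field over the template is then smoothed with a Gaussian kernel (width
   4 times the mean point spacing) and reprojected, twice. This removes
   the per-point tangential sliding noise of the mixture registration
   while preserving the smooth anatomical displacement.
6. **Groupwise refinement** (`refine_correspondence()`). After a first
   correspondence, each sample is replaced by its rank-`d` model
   reconstruction projected back onto that sample's true surface, and the
   mean/model re-estimated; `d` is locked at the first pass from the
   requested variance fraction. This is the compactness-driven
   correspondence optimization idea of the description-length school:
   because every corresponded point always lies exactly on its source
   surface, the loop can only concentrate variance into few modes if the
   surfaces genuinely admit a compact joint parameterization. On synthetic
   two-mode populations this step moves the two-mode variance share from
   roughly 96% to beyond 99%; without it, residual registration curvature
   of a few percent is unavoidable for any one-shot pairwise method we
   measured (CPD with projection, pure closest-point transport, and a
   second pass from the estimated mean all plateau near 95–96%).
7. **Vertex lift.** The point correspondence is extended to the template
   mesh vertices: a TPS per sample maps the template points to their
   corresponded locations, the template vertices follow, and the images
   are projected onto the sample surface. The model is then built over
   vertices, so every instance comes with a mesh — the template
   connectivity over the instance points — that passes through the
   instance exactly. A short vertex-level refinement (ten passes by
   default) follows; the depth is a deliberate compromise, because
   further passes keep tightening the training compactness while sliding
   vertices away from high-curvature regions, which measurably degrades
   generalization to held-out shapes.
8. **Rigid GPA and PCA.** Generalized Procrustes analysis removes rigid
   differences only — no scale normalization, because absolute size
   matters for FE models; size variation is then simply one of the linear
   modes. PCA of the flattened aligned sets gives the modes; modes are
   retained to a cumulative variance fraction (default 0.95, ties kept).

`correspond()` returns template-indexed sets, so point `i` of every sample
refers to the same anatomical location and the mean is well defined. The
average mesh stored on the model is the template warped by a thin-plate
spline (TPS, 3-D kernel `U(r) = r`) from the template points to the mean
points; `instance_mesh()` re-warps it to any instance, preserving the
template's connectivity.

## Fitting the model to a segmentation

`ssm_fit()` is an active-shape fit. Pose is initialized by coarse
alignment plus similarity CPD against surface samples of the target; the
alternating loop then (1) finds closest points on the target surface for
the posed instance, (2) refines the similarity pose by Procrustes on those
pairs, (3) solves the Tikhonov-regularized least-squares mode update
`b_i = p_i \sigma_i^2 / (\sigma_i^2 + \lambda_b)` with per-mode clamping at
`3\sigma_i`, until the mean point movement drops below `tol` (default
1e-3 mm). The clamp is what produces the hole-filling behaviour: surface
points pulled into mask defects cannot drag the fit outside plausible
anatomy.

Because principal-axes initialization can flip when the target's
eigenvalue order differs from the mean's (nearly axis-symmetric shapes),
the fit is *multi-started*: an axes-based and a centroid/size-only
initialization, each tried both through CPD pose estimation and fed
directly to the alternating loop (CPD itself can rotate a good start into
a mirrored basin for extreme targets). The run with the lower final
surface residual wins, and if even the best residual exceeds 2% of the
target's size — far above any normal fit — extra starts rotated half a
turn about the mean's principal axes are tried. On our synthetic femora a
mirrored fit converges to a residual an order of magnitude larger than a
correct one, so the selection is unambiguous.

Closest-point targets carry no information along directions in which a
mode slides tangentially to the surface — and the condyle-separation mode
of a femur is about two-thirds tangential. For system-identification
experiments on noiseless model-generated targets, `polish = TRUE` adds a
damped point-to-plane refinement of the mode weights (normal-offset
constraints with a line search, accepted only while the surface residual
decreases), which restores the tangential components and makes mode-weight
recovery sharp. It is off by default: on degraded segmentations the same
freedom lets the fit chase surface noise.

Defaults and units: `clamp_sigma = 3` (dimensionless, in mode SDs),
`lam_b = 1` (mm², balancing fidelity and plausibility; set it near zero
for noiseless recovery experiments), `tol = 1e-3` mm, at most 50
iterations per start; the iterations run on at most `fit_budget = 600`
model points (proper least squares in the subsetted, non-orthonormal
basis), with the final instance always using all points.

## Masks, surfaces, and metrics

Masks follow NIfTI practice: 0-based voxel indices, world position
`origin + index * spacing`, voxel-centre convention, spacing positive
(axis flips are folded into the stored array on read). Oblique affines are
rejected.

Surface extraction uses marching tetrahedra on a 5-tetrahedra cell
decomposition whose orientation alternates in a checkerboard pattern, so
shared cell faces carry the same diagonal and the mesh is watertight by
construction. The binary field is pre-smoothed with a Gaussian
(`sigma = 1` voxel) before extraction — without it, the staircase surface
of a digitized ball overestimates the analytic area by well over 10%; with
it, the area error is a few percent. If smoothing would erase a tiny blob
(no crossing left), extraction falls back to the raw binary field, which
keeps single-voxel objects representable. The largest connected component
is kept and the mesh is oriented outward (positive signed volume).

Voxelization is the inverse: a voxel is foreground iff its centre is
inside the closed surface, decided by ray-parity with one ray per (y,z)
row and a tiny irrational row offset so edge-grazing intersections have
measure zero.

The four segmentation metrics follow the usual definitions: Dice
`2|A∩B|/(|A|+|B|)` on identical grids (IoU is reported alongside, as the
two are often conflated); Hausdorff as the maximum of both directed
vertex-to-surface distance sets; average distance as the mean of the
concatenated directed sets; and the percentage of predicted surface area
farther than 1 mm from the truth, with each vertex owning one third of its
incident triangle area. Distances are point-to-triangle (not
point-to-vertex), computed by an exact region-based closest-point kernel
with a uniform-grid acceleration for large meshes; unit tests pin the
implementation against an exhaustive, independently coded search to
1e-9 mm.

## Cartilage extrusion

The contact patch is the largest connected set of bone faces whose
centroids lie within `max_distance` of the articular surface. A regular
`nu x nv` grid over the patch's least-squares plane is projected onto the
bone (closest point), giving a quad patch whose nodes lie exactly on the
surface; the target element size can be given directly (presets 2 / 1 /
0.5 mm). Each node is carried to the articular surface along its
area-weighted normal (ray casting, nearest-point fallback when the ray
misses), the thickness floored at `min_thickness = 0.1` mm to avoid
degenerate elements at cartilage margins, and the column divided into
`n_layers = 5` equal segments. This captures the spatial variation of
cartilage thickness while keeping the interface nodes bit-identical to the
patch nodes, so bone and cartilage share nodes in the FE model. Scaled
Jacobians at the 8 trilinear corner frames, inverted-element counts and
thickness statistics come from `hex_quality()`; `write_inp()` emits
`*NODE`, `*ELEMENT TYPE=C3D8P` (pore-pressure hexahedra) and the node/
element sets, and is round-trip tested against `read_inp()`.

## 1-D SPM

Stance-phase trajectories are resampled to a common base (101 nodes over
0–100% by convention). The two-sample test computes the pointwise
pooled-variance t statistic (Welch optional), estimates the residual
smoothness with the standard kernel-free estimator
`FWHM = sqrt(4 log 2) / RMS gradient` of the unit-variance-normalized
residuals, and thresholds `|t|` at the random-field-theory level: the
smallest `u` with expected Euler characteristic
`P(T > u) + R * sqrt(4 log 2)/(2\pi) * (1 + u^2/\nu)^{-(\nu-1)/2}` at most
`alpha/2` per tail, `R = (Q-1)/FWHM` resels, solved by bisection. Two
properties anchor the implementation: as `FWHM → ∞` the threshold equals
the two-tailed Student quantile (identity to 1e-4 in the tests), and under
the smooth Gaussian null (FWHM 20, 9 vs 9 curves, 1000 replicates) the
empirical rejection rate is within [0.03, 0.07] at `alpha = 0.05`. The
threshold is additionally cross-checked against a Monte-Carlo oracle of
the null field maximum (agreement within 10%); no external SPM
implementation is shipped or required.

The trajectory generator smooths white noise with a Gaussian kernel whose
SD is `FWHM / sqrt(8 log 2)`, then rescales to unit variance per node, so
the generated field's RFT smoothness equals the requested FWHM; the
estimator recovers it within 15% on ensembles.

## The synthetic population

`synth_population()` builds distal-femur-like implicit surfaces: two
superellipsoids (exponent 2.5) for the condyles and a capped cylinder for
the shaft, blended with a soft-minimum (log-sum-exp, `k = 6`), evaluated
on a regular grid (default 1.5 mm) and extracted by marching tetrahedra.
Like a real distal femur the shape is asymmetric — the medial condyle is
15% larger and the shaft axis sits anterior to the condylar centre — which
both mimics anatomy and makes the principal-axes orientation of every
sample unambiguous for coarse alignment. The default latent modes are
condyle width (mean 12 mm, SD 1.0 mm) and condyle separation (mean 26 mm,
SD 1.8 mm), coefficients of variation of 7–8%, a typical anatomical
spread; the other parameters are fixed. Degradation
(`synth_degrade()`) emulates a network's output: voxelization on a 0.5 mm
grid (an anisotropic 0.36/0.36/0.7 mm preset mirrors knee-MRI
resolution), vertex jitter before voxelization, carved spherical holes at
surface-adjacent centres, and random flips of boundary voxels.

What the generator does *not* emulate: real cortical/trabecular intensity
structure, segmentation errors correlated with anatomy (network errors
cluster at the cartilage interface), pathological shape variation beyond
the two smooth latent modes, and inter-rater ambiguity in the ground
truth. Passing the synthetic checks therefore demonstrates that the
machinery is correct and self-consistent — not that the same accuracy
numbers would be obtained on clinical data.

## Numerical choices and problem sizes

* Correspondence budgets: the package default is `n_points = 5000` per
  the dense-sampling idea; the shipped tests and the acceptance script use
  350–500 template points with 3x denser targets, which our experiments
  show already drive registration noise to ~0.15 mm RMS on 20 mm-scale
  shapes, and keep a full 30-shape model build in minutes on one core.
* CPD EM stops on relative log-likelihood change below 1e-6, on reaching
  `max_iter`, or when `sigma^2` hits its floor (exact-match limit). The
  non-rigid coherence penalty enters the M-step as `lam * sigma^2`, so the
  suppression of deformation at very large `lam` is strong but not exact
  once `sigma^2` has annealed; the tests assert a >= 20-fold suppression
  rather than a fixed displacement bound.
* `remesh_template()` is accurate to well under 0.1 mm on smooth closed
  surfaces; features narrower than the output edge length (the deep
  intercondylar groove at coarse budgets) are necessarily blunted.
* Degenerate inputs: empty masks, non-manifold meshes, coplanar landmark
  sets, zero-variance residual fields and empty patch selections raise
  errors naming the offending entity; two empty masks define Dice 1 with
  a warning.
* All generators and the pipeline are seed-deterministic; `with_seed()`
  restores the caller's RNG state, and every stage seed is derived from
  the single pipeline seed.

## Known limitations

* The adjusted surface lives in the model span: pathology outside the
  training variation is smoothed away. This is inherent to SSM adjustment,
  and is the price of hole-filling.
* Correspondence is defined by registration plus groupwise refinement, not
  by anatomical landmarks; labels on near-symmetric or featureless regions
  (shaft walls) are only as meaningful as the model's smoothness prior.
* The quad-patch construction assumes the contact patch projects
  one-to-one onto its least-squares plane; strongly curved or folded
  patches would need an atlas of patches.
* INP export covers geometry and sets only — material assignment, contact
  and loading are intentionally out of scope.
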