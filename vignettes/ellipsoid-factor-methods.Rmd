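---
title: "Measuring local plate/rod geometry in trabecular bone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring local plate/rod geometry in trabecular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneshape)
```

## The problem

Trabecular (spongy) bone is a network of struts ("rods") and sheets
("plates"). In osteoporosis the micro-architecture remodels, and a
long-standing hypothesis holds that plates convert to rods as bone is lost.
The classical summary statistic for this, the structure model index (SMI),
is derived from how the total bone surface area responds to a small outward
offset, which makes it a single global number that is also badly confounded
by bone volume fraction and by the saddle-shaped (hyperbolic) patches that
dominate real trabecular surfaces: those patches *shrink* under dilation.

The ellipsoid factor (EF) measures shape locally instead. For each
foreground voxel, find the largest ellipsoid that contains the voxel while
fitting inside the bone; with sorted semi-axes $a \le b \le c$ the voxel's
score is

$$\mathrm{EF} = \frac{a}{b} - \frac{b}{c} \in [-1, 1],$$

which is $-1$ for an ideal plate ($a \ll b = c$), $+1$ for an ideal rod
($a = b \ll c$) and $0$ for spheres and for intermediate shapes with
$a/b = b/c$. EF is a difference of ratios, hence scale-free and a priori
independent of bone volume fraction. This package implements the complete
EF pipeline, a mesh-based SMI (with its convex/concave split
SMI\textsuperscript{+}/SMI\textsuperscript{-}) for comparison, and a family
of synthetic phantoms with known ground truth so that every stage is
testable without image data.

## The EF pipeline

One **run** consists of seeding, ellipsoid fitting, and per-voxel
assignment.

**Seeding.** Ellipsoids start as small spheres at seed points. Two
strategies are available: the *distance ridge* (efficient, favours thick
regions) and a *topology-preserving skeleton* (reaches thin features).
The ridge is computed as the morphological closing minus opening of the
Euclidean distance transform $D$ with a flat $3^3$ element, thresholded at
0.5 voxels — both the element size and the threshold are package choices,
since only the closing-minus-opening construction itself is prescribed.
Two refinements were forced by measurement on voxelized phantoms: a ridge
voxel must also be *near-maximal* in its 26-neighbourhood (no neighbour
exceeds $D$ by more than 0.5) and either lie clear of the boundary layer
($D > 1.5$) or be an exact plateau maximum (which keeps one-voxel-thin
structures). Without this, the staircase surface of a voxelized ball
produces ridge responses on the boundary that seed useless sub-voxel
ellipsoids. The skeleton is a sequential thinning that deletes simple
points (removal provably preserves foreground 26-topology and background
6-topology) in order of increasing $D$, keeping curve endpoints; the
contract is topology preservation plus medial position, not agreement with
any particular published thinning's voxel set. The
`skeleton_points_per_ellipsoid` parameter decimates the merged seed list in
lexicographic scan order; 1 keeps every seed (recommended for production),
the quick-look default of 10 keeps a tenth.

**Fitting.** From each seed a sphere grows by `sampling_increment`
(default $1/2.3$ voxels) until a *collision*: at least
`contact_sensitivity` (default 1) of `n_vectors` (default 100) random
surface points land on background, where points are distributed uniformly
with respect to surface area (directions drawn on the unit sphere, mapped
to the ellipsoid, rejection-corrected by the area Jacobian) and everything
outside the image grid is background. Sampling stops as soon as the
sensitivity count is reached; the mean of exactly those hits is the contact
vector. This early stop matters: averaging all hits of a full sample
cancels between the two faces of a thin symmetric plate and destroys the
axis estimate. Because a handful of hits is a noisy direction, the
direction is then re-estimated from a denser ($10\times$) sample of the
collided state. The first semi-axis is set along the contact vector, the
ellipsoid is contracted by 0.95 (a package constant: small enough to
re-enter the foreground, large enough not to oscillate), and growth
continues with the two in-plane axes until the next collision, whose
contact vector (projected into the plane) orients the second axis — so the
third axis points along the locally freest direction, e.g. down a rod.

**Stochastic refinement** then hill-climbs for a larger ellipsoid for up to
`max_iterations` (default 50) consecutive failures or $10\times$ that many
total attempts. Each proposal couples one increment of growth of a random
semi-axis with one of: nothing, a small rotation (uniform angle in
$[0, 0.1]$ rad about a random axis), a spin of the in-plane axes by an
arbitrary angle about the contact axis (this is how "growth directions
recalculated at each iteration to be random, but in the contact plane" is
realized — it lets the long axis of a rod be discovered), or a translation
(uniform in a ball of one increment, clipped so the centre never drifts
more than `max_drift` — one 3D voxel diagonal, $\sqrt 3$ — from the seed).
A proposal is kept if and only if it is collision-free; since its volume
necessarily grew, accepted volumes increase monotonically. Coupling growth
into the perturbations is a deliberate design choice: under a
keep-only-if-larger rule, pure rotations and translations (volume
preserving) could never be accepted and would be dead weight. A fit is
discarded as invalid when the seed's initial sphere collides even after one
halving (sub-voxel structure), or when more than half of a fresh surface
sample falls outside the image bounds.

**Assignment and averaging.** Every foreground voxel receives the EF of
the largest-volume ellipsoid containing its centre (ties go to the lower
ID), or NaN if none; per-ellipsoid bounding boxes accelerate the scan and
the result is tested to equal the brute-force all-pairs scan exactly. An
optional generalization averages the $n$ largest containing ellipsoids per
voxel (`average_largest_n`, default 1). Because fitting is stochastic,
results are averaged over `repetitions` runs (production recommendation:
6) with a NaN-aware per-voxel mean. Convergence is reported as the median
and maximum absolute change of the running mean between consecutive runs,
computed over the voxels covered in *every* run so far. Restricting to
that stable core is a package decision: a voxel covered only in, say, runs
5 and 6 contributes a coverage artefact of up to one full EF unit to the
maximum, which says nothing about convergence of the average. On a $64^3$
gyroid at the recommended settings the median and maximum change between
runs 5 and 6 are about 0.014 and 0.15, comfortably below the published
guide levels of 0.15 and 0.4.

```{r ef-example, eval = FALSE}
gy <- make_gyroid(period = 24, level = 0.4, dims = 64)
set.seed(1)
res <- ef_pipeline(gy, production_params())
summary_stats(res)
res$convergence
```

## SMI for comparison

The surface is triangulated by marching tetrahedra on the binary grid after
block-resampling (factor 2) — resampling turns the binary field into a
graded occupancy whose interpolated iso-surface is far smoother than the
raw voxel surface — followed by one Laplacian pass with relaxation 0.5.
("Mesh smoothing 0.5" is ambiguous between an iteration count and a
relaxation factor; one pass at factor 0.5 is the declared reading, and the
sphere-area error of about 0.6% supports it.) With
$S$ the surface area, $V$ the enclosed volume and
$S' = (S(\mathrm{d}r) - S)/\mathrm{d}r$ the area response to displacing
each vertex by $\mathrm{d}r = 1/100$ voxel along its normal,

$$\mathrm{SMI} = \frac{6\,V S'}{S^2},$$

which is 4 for a sphere, 3 for an infinite cylinder and 0 for an infinite
plate (a plane's area does not change under offset). Per-triangle area
changes split SMI exactly into SMI$^+ \ge 0$ (convex) and SMI$^- \le 0$
(concave, the hyperbolic contribution; strictly negative on a gyroid).

Grid-spanning phantoms stand in for the infinite reference shapes. Their
artificial end caps on the image bounding box are excluded from $S$ and
$S'$; measurement showed two further steps are needed to keep cap effects
out of the open-shape values: triangles with *any* vertex on a bounding
plane are excluded (dropping the tilted junction band between surface and
cap), bounding-plane vertices are pinned during smoothing, and vertex
normals are accumulated from retained faces only. Without these, rim
stretching inflates the cylinder's SMI by roughly $+0.4$. Measured values:
spheres of radius 8–12 give 3.77–3.84, grid-spanning cylinders of radius
6–10 give 3.08–3.30, slabs of thickness 6–10 give 0.13–0.54 (voxelization
noise around the analytic 0).

## What the phantoms do and do not establish

The generators produce spheres, rods, plates, axis-aligned ellipsoids,
gyroid lattices ($\sin x'\cos y' + \sin y'\cos z' + \sin z'\cos x' >$
level; connected, hyperbolic-surfaced, trabecular-like in topology), and a
labelled disjoint rod/plate lattice used as sign ground truth. Inclusion
tests use voxel centres with no partial-volume antialiasing, matching the
binary input assumption of the fitter. Defaults (gyroid period 24 voxels,
level 0.4, $64^3$ grids, rod radii 4–8, plate thicknesses 4–8) put feature
radii at 3–6 voxels, the scale the original parameter defaults were tuned
for and comparable to the 5–8 pixel trabecular thickness of the human
vertebral scans that motivated the method's convergence guidance.

Green phantom tests establish that the geometry engine recovers known
shapes: rods give median EF $> 0.5$, plates $< -0.5$, spheres near 0, and
at least 90% of labelled lattice voxels get the correct EF sign. They do
not establish biological validity on real micro-CT data: phantoms have
clean binary boundaries, no noise, no partial-volume fuzz, no curvature
gradients, and no marrow-space clutter. The preprocessing ops (3D ball
median filter, strict `>` threshold) mirror a real protocol (radius 3,
level 75 on 8-bit data) but their biological adequacy is out of scope here.

## Numerical choices and degenerate inputs

* Coordinates: voxel centres at integer $(z, y, x)$, 0-based; all geometry
  is continuous in that frame; only reporting multiplies by the spacing.
  Anisotropic voxels are rejected outright rather than mis-scaled.
* Outside the grid is background everywhere (distance transform, contact
  detection, mesh closure) — conservative, and consistent with discarding
  ellipsoids that leave the image.
* Thresholding is strict (`> level`); a voxel exactly at the level is
  background. Stated once, tested once.
* The exact Euclidean distance transform uses the separable
  lower-envelope algorithm on a zero-padded grid and is tested against
  exhaustive search.
* Repeated rotation proposals re-orthonormalize the orientation frame;
  without this, rounding error in a frame column used as a rotation axis
  compounds exponentially and collapses the frame (observed, fixed,
  regression-guarded by the orthonormality invariant test).
* Equal-volume claim ties resolve to the lower ellipsoid ID; equal-volume
  proposals keep the incumbent (no drift without improvement).
* The EF mode statistic uses fixed histogram bins of width 0.05 on
  $[-1, 1]$, lowest bin winning ties.
* Degenerate inputs error early and explicitly: empty foreground (seeding,
  meshing, pipeline), empty masks, non-orthonormal axes, unsorted
  semi-axes, negative radii.

## Known limitations

* A single fitted ellipsoid cannot exceed about $0.95\,R$ in a sphere of
  radius $R$ (two 0.95 collision contractions and the discrete contact
  radius), so single-run filling saturates near 80–85% on a solid ball —
  the practical reason multiple seeds and runs are averaged. Reported
  filling percentages should be read with that ceiling in mind.
* Per-seed fits in rods are bimodal: the long axis is found by stochastic
  in-plane reorientation and sometimes locks in misaligned. The per-voxel
  largest-containing rule and run averaging absorb this, but single-fit
  semi-axes are not reliable measurements.
* Grayscale (fuzzy-boundary) input is unsupported; binary segmentation
  quality bounds everything downstream.
* The mesh-based SMI inherits voxelization bumps; its absolute values on
  thin structures carry $\pm 0.3$-scale discretization error, which is the
  tolerance used throughout the tests.
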