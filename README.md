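# boneshape

Local shape analysis of trabecular bone in 3D binary images: the
**ellipsoid factor (EF)** — a per-voxel, scale-free measure of where a
structure sits on the plate–rod continuum — together with the mesh-based
**structure model index (SMI, SMI+, SMI−)** for comparison, and synthetic
phantoms with known ground truth so the whole pipeline can be validated
without any image data.

## Who this is for

Skeletal biologists and image-analysis researchers quantifying trabecular
micro-architecture from micro-CT: does bone loss convert plates into rods?
SMI, the classical answer, is a single global number confounded by bone
volume fraction and by the saddle-shaped surfaces of real trabeculae. EF
answers locally and per voxel instead.

## The measure

For each foreground voxel, find the largest *locally maximal ellipsoid*
(grown stochastically from medial seed points) that contains the voxel and
fits inside the bone. With sorted semi-axes *a* ≤ *b* ≤ *c*,

    EF = a/b − b/c   ∈ [−1, 1]

is −1 for an ideal plate (a ≪ b = c), +1 for an ideal rod (a = b ≪ c), and
0 for spheres and intermediate shapes. Per-voxel EF maps are averaged over
repeated runs with convergence diagnostics (median/maximum change of the
running mean per run), and ellipsoid semi-axis ratios can be inspected on
Flinn (peak) plots, where EF is constant along diagonals.

SMI is computed from a triangulated surface as `6·V·S′/S²` where `S′` is
the surface-area response to a small normal offset — 4 for a sphere, 3 for
an infinite cylinder, 0 for an infinite plate — and splits exactly into a
convex part SMI+ and a concave part SMI− (negative on hyperbolic surfaces,
which is precisely why SMI misreads trabecular bone).

## Worked example

A gyroid lattice is a connected, saddle-surfaced structure that mimics
trabecular topology. Measure EF and SMI on it:

```r
library(boneshape)
gy <- make_gyroid(period = 24, level = 0.4, dims = 64)
gy
#> <binary_volume> 64 x 64 x 64 (z, y, x), spacing 1
#>   foreground 95491 / 262144 voxels (36.4%)

set.seed(42)
res <- ef_pipeline(gy, production_params())   # all seeds, 6 runs averaged
res
#> <ef_result> 6 run(s), filling 94.8%, 19422 ellipsoids
#>   final median/max EF change: 0.014 / 0.153

unlist(summary_stats(res))
#>     min_ef     max_ef  median_ef    mode_ef  n_covered
#> -0.5193076  0.8094316  0.4157033  0.4750000 90531
res$convergence
#>   run median_change max_change filling_percentage
#> 1   2    0.04987531  0.5615189           92.35739
#> ...
#> 5   6    0.01424948  0.1526073           94.80579

structure_model_index(make_mesh(gy), exclude_boundary = TRUE)
#> <smi_result> SMI 1.673 (SMI+ 3.335, SMI- -1.662); S 31238.0, V 92562.5
```

Reading the numbers: 94.8% of bone voxels were covered by at least one
valid ellipsoid over six runs; the median EF of 0.42 says the gyroid at 36%
volume fraction is predominantly rod-like locally, while EF values from
−0.52 to +0.81 coexist — shapes across the whole plate–rod continuum, which
a single SMI of 1.67 cannot express. The median change of 0.014 between
runs 5 and 6 (recommended guide level: below 0.15) indicates the six-run
average has converged. The strictly negative SMI− (−1.66) quantifies the
hyperbolic surface patches that shrink under dilation.

On analytic phantoms the same code recovers the references: `make_sphere()`
→ EF ≈ 0 and SMI ≈ 4; `make_rod()` → median EF > 0.5 and SMI ≈ 3 (caps
excluded); `make_plate()` → median EF < −0.5.

Real image stacks enter through `read_tif()` (multi-page grayscale TIFF),
`median_filter3()` and `threshold_volume()`; results leave as 32-bit float
TIFFs (NaN = uncovered), CSV tables and Flinn plots via `cmd_ef()` /
`cmd_smi()` or the `inst/exec/boneshape` command-line wrapper, which logs
every parameter and RNG seed for replay.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch — the SMI of voxelized sphere/cylinder/slab reference phantoms, the
EF range bound across full pipeline runs on four phantom families, and the
median/maximum per-voxel EF change contributed by the sixth run of a
six-run average on a 64³ gyroid (three RNG seeds, median reported) — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It runs in about a minute on one CPU and uses only the installed package.
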