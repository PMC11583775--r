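---
title: "Quantifying partial and total geometric errors of a simulated medical 3D-printing pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying partial and total geometric errors of a simulated medical 3D-printing pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Producing a patient-specific anatomical model by 3D printing is a chain of
lossy steps: a CT scan of the anatomy, a threshold segmentation of the scan,
digital editing (typically smoothing) of the segmented surface, and the
physical print. Each step deforms the geometry a little. Quality assurance
for point-of-care printing needs the error of each step *separately* —
otherwise there is no way to know which knob to turn — and a way to combine
them into a statement about the finished model.

`printqa` reproduces this error-budget methodology entirely on the desk. A
femur-like digital phantom plays the role of the anatomy; simulators stand in
for the scanner and the printer; an open surface-deviation engine replaces
commercial inspection software. Because every stage is synthetic, the ground
truth is known exactly at every hand-off, and the full study runs in minutes
on one CPU.

The three partial errors follow the standard taxonomy:

* **SegE** (segmentation error): ground-truth phantom vs. the direct
  segmentation result;
* **DEE** (digital editing error): direct segmentation vs. the smoothed
  "print-STL";
* **PrE** (printing error): print-STL vs. the (simulated) printed model.

Each comparison yields signed surface deviations $\Delta S$ sampled over the
analyzed surface, summarized by the mean $\overline{\Delta S}$ (negative =
analyzed object smaller than reference) and the width of the
$\pm 3\sigma$ interval, $6\sigma\,\Delta S$. The partial errors combine by
Gaussian error propagation, assuming independence between stages:

$$\Delta mean_{Total} = \Delta mean_{SegE} + \Delta mean_{DEE} + \Delta mean_{PrE}$$
$$\sigma_{Total} = \sqrt{\sigma_{SegE}^2 + \sigma_{DEE}^2 + \sigma_{PrE}^2}$$

Means can cancel; variances only grow. `propagate_total()` implements
exactly this and asserts $\sigma_{Total} \ge \sigma_i$ for every stage. No
covariance terms are modelled — the independence assumption is inherited
from the methodology, documented here, and not tested.

## The phantom

`femur_phantom()` builds the test specimen from a signed-distance
construction: a box shaft (flat faces, sharp edges), a capsule neck at 45°,
a spherical head, smooth-union fillets at the junctions (concave blends) and
a seeded set of shallow Gaussian bumps on the head for freeform detail. The
solid is cut flat at $z = 0$ so it rests on a build plate. The surface is
extracted from the distance field by marching tetrahedra, so the mesh is
watertight by construction and byte-deterministic for a fixed
`(complexity, seed)`.

`complexity` controls only the sampling resolution of the distance field
(cell size $1.6/\text{complexity}$ mm); the enclosed volume converges with
refinement (complexity 3 and 5 agree to about 0.01%). The default study uses
complexity 3 (≈ 0.53 mm cells, ≈ 280k triangles, ≈ 52,000 mm³, extents
≈ 55 × 32 × 88 mm).

## The CT simulator

`simulate_ct()` models the acquisition in four steps:

1. **Partial volume.** Per-voxel occupancy fractions are computed with 16
   vertical sub-rays per voxel column and *exact* integration of the inside
   intervals over each voxel's z extent. This is the box component of the
   slice sensitivity profile, and it makes thick slices exhibit partial
   volume exactly.
2. **HU mapping.** $HU = -1000 + f\,(HU_{object}+1000)$ with
   $HU_{object} = 200$ by default, so air is −1000 HU and the half-occupancy
   surface sits at −400 HU. The object HU is a calibration choice: with it,
   the optimal segmentation threshold of the synthetic pipeline lands near
   −400 HU and the surface starts to disintegrate a little above 0 HU,
   mirroring the behaviour of a plastic phantom scanned in air. It is
   configurable.
3. **Reconstruction kernel.** A Gaussian point-spread function applied
   *in-plane only* (the kernel is a 2D reconstruction filter; through-slice
   resolution belongs to the slice profile). The soft-tissue kernel defaults
   to FWHM 1.2 mm with 15 HU noise; the bone kernel is sharper (0.6 mm) with
   an unsharp-mask edge boost (weight 0.5) but noisier (60 HU). These
   defaults are stylized: they are chosen to reproduce *orderings* (bone
   sharper and noisier than soft), not any scanner's absolute values.
   Additionally, a Gaussian slice-profile component of FWHM equal to one
   slice thickness (σ = 0.5 voxel along z) is applied, and the noise is
   given the same z correlation: real slice profiles are not perfect boxes
   and overlapping profiles correlate noise between adjacent slices. Set
   `slice_profile_fwhm_factor = 0` for an idealized box profile.
4. **Noise.** Seeded additive Gaussian noise of the kernel's amplitude, then
   clamping to the scanner range [−1024, 3071] HU.

The voxel model: values live at voxel centers, the z axis is the slice axis,
arrays are indexed `(slice, row, col)`, and the world coordinate of voxel
`(i, j, k)` (1-based) is `origin + ((k-1)dx, (j-1)dy, (i-1)dz)`.

## Segmentation

`segment_threshold()` marks voxels at or above the threshold as object and
extracts the surface with sub-voxel linear interpolation on the continuous
HU field, matching the smooth threshold response of interactive clinical
tools; a `surface = "binary"` flag extracts the 0.5 level of the binary mask
instead, for studying voxel staircase in isolation. Iso-surfacing uses
marching tetrahedra on the six-tetrahedron decomposition of each grid cube;
all cubes share the same main diagonal, so neighbouring cubes split their
common face identically and the surface is closed whenever the grid boundary
is air (the volume is padded with one air layer to guarantee this).

`island_policy = "keep_all"` keeps every closed component — this is what
reproduces island formation in noisy bone-kernel data at high thresholds —
while `"largest_component"` keeps the largest solid. The volume cut-off
(default 30,000 mm³) flags segmentations too eroded for meaningful deviation
analysis; equality passes, only volumes strictly below the cut-off are
excluded. These cells appear as `NA` gaps in the study tables.

## Smoothing profiles

Commercial editing tools expose incompatible smoothing scales, and their
algorithms are unpublished. The package therefore ships three *profiles*
that reproduce the study's level-to-parameter mappings without claiming
algorithmic fidelity:

| profile | method | low | medium | high |
|---|---|---|---|---|
| `slicer_like` | median filter on the HU volume, re-extract | 1 mm | 3 mm | 5 mm |
| `brainlab_like` | Taubin mesh smoothing, `round(10·factor)` iterations | 0.66 | 1.33 | 2.00 |
| `d2p_like` | median filter | 1 mm | — | — |

Whether the real tools smooth the label volume or the mesh is unknown; both
paths are provided and profile-selected. The Taubin λ/μ weights are 0.5 and
−0.45: the μ step inflates back most of the Laplacian shrinkage but leaves a
mild, monotone net shrink concentrated at edges and corners, which is the
qualitative behaviour the profiles must reproduce. Millimetre kernels are
converted per axis to odd voxel windows, rounding up; a kernel below one
voxel in every axis warns and returns the input unchanged.

`dee_metrics()` compares print-STL to direct segmentation: relative change
of enclosed volume and of the binary-STL file-size proxy
$F_i = 84 + 50\,n_{triangles}$ bytes (the exact binary STL layout, used as
the surface-complexity measure), plus the signed surface deviation.

## Print simulator

`simulate_print()` deforms the print-STL surface directly (mesh-to-mesh, no
re-voxelization):

* **Staircase**: each point's height above the base is pulled halfway toward
  the floor of its 0.3 mm print layer. The map is monotone in z, so the
  deformation cannot self-intersect.
* **Warping**: vertical lift-off
  $w = A\,e^{-d/\lambda}\,\max(0, 1 - z/h)$ where $d$ is the horizontal
  distance from the base-footprint boundary inward (computed by an exact 2D
  Euclidean distance transform of the footprint), $\lambda$ = 10 mm decay,
  $h$ = 5 mm affected height. Corners and edges of the base lift most —
  the signature of poor bed adhesion. Amplitudes above $h$ would fold the
  surface and are rejected.

The default study ships two printers: `accurate` (no warp — a well-adhered,
heated-bed machine) and `warped` (mean amplitude 1.2 mm, the millimetre scale of
thermoplastic lift-off under poor bed temperature control).
Replicates draw their amplitude around the printer mean with 15% coefficient
of variation, emulating bed-position effects, and record the draw.

## Deviation engine

`signed_surface_deviation()` samples the analyzed surface (all vertices when
they fit the budget, otherwise seeded area-weighted sampling; default budget
100,000), finds for each sample the exact closest point on the reference
surface via a bounding-volume hierarchy, and signs the distance by a solid
inside/outside ray-parity test: +1 outside the reference, −1 inside. The
solid test, rather than a local-normal dot product, is what makes internal
islands carry negative deviations robustly. The analyzed→reference
correspondence direction is the default and fixes the sign convention
(negative mean ⇒ analyzed smaller); the reverse direction is available
behind a flag and preserves that sign convention.

`icp_align()` provides rigid (no scaling) alignment: centroid and
principal-axes initialization over all four proper axis-sign combinations,
then iterated exact closest-point correspondences with an SVD re-fit until
the RMS improves by less than 10⁻⁶ mm (cap 200 iterations). A final RMS
above 25% of the reference bounding-box diagonal means the surfaces cannot
be brought into correspondence and is an error — the same situation that
motivates the volume cut-off. In the synthetic study all stages share one
coordinate frame, so the study runners skip alignment by default
(`align = TRUE` enables it); the engine itself recovers random rigid motions
(≤ 30°, ≤ 20 mm) to ≈ 10⁻⁵ mm RMS.

Results export to a plain-text table (`write_deviation_ascii()`): header
lines with the summary statistics, then `x y z deviation` per sample at six
decimals, lossless on re-import at that precision.

## The study runners

`study_config()` holds the full design: 5 slice thicknesses × 2 kernels,
7 thresholds (−800, −600, −400, −200, 0, 100, 200 HU — a non-uniform grid
containing every threshold the tables discuss), 3 profiles, the DEE cell
selection (bone kernel, −600 HU, thicknesses 0.4/1.5/5.0 mm), printers and
replication. Every stage derives its own RNG stream from the master seed;
rerunning a configuration reproduces every table bit-for-bit.

* `run_sege_sweep()`: 3 × 10 × 7 = 210 records; per cell: volume, ΔV rel,
  $F_i$, component count, cut-off flag, and deviation statistics vs. the
  phantom. The threshold-segmentation stage is identical across the
  software profiles (profiles differ in smoothing), so profile rows share
  cell values.
* `run_dee_study()`: (3+3+1) profile-levels × 3 thicknesses = 21 print-STL
  records with ΔFi rel, ΔV rel and deviation vs. the direct segmentation.
* `run_pre_study()`: printers × 5 replicates, deviation of each printed
  model vs. the print-STL (the phantom mesh is the construction STL).
* `run_total_error()`: two named presets — `config_1_optimal` (0.4 mm
  slices, soft kernel, −400 HU, low smoothing, accurate printer) and
  `config_2_worst_case` (5.0 mm slices, −600 HU, high smoothing, accurate
  printer) — each propagated from one SegE cell, one DEE cell and the
  replicate-averaged accurate-printer PrE (mean of means, RMS of sigmas).
  The presets are representative best-case and degraded-input parameter
  choices, labelled as such in the output.

Each runner returns a tibble with an `autoplot()` method; deviation and
total-error objects have `tidy()`/`glance()` methods.

## Numerical choices and degenerate inputs

* Vertices are double precision internally; 32-bit floats only at STL
  serialization (the format mandates float32).
* Zero-area triangles are dropped on STL load (with a message) — iso-surface
  extractors can emit them and they corrupt normals. No further mesh repair
  is attempted.
* Marching tetrahedra nudges grid values lying exactly on the iso level by
  10⁻⁹ relative units, so interpolation weights stay in (0, 1) and no
  degenerate vertices are produced.
* Sub-rays in the voxelizer carry a fixed irrational in-plane jitter so they
  cannot hit triangle edges exactly; rays with odd crossing parity (possible
  only for defective meshes) are skipped and counted.
* The inside/outside ray uses a fixed irrational direction for the same
  reason.
* The volume cut-off comparison is `>=` (equality passes), per its stated
  definition ("less than" excludes).
* An empty segmentation (no voxel at or above threshold, or an empty
  iso-surface) is an explicit error; the sweep records such cells as
  excluded with zero volume and continues.

## What the synthetic study does and does not show

The generator reproduces the *structure* of the physical experiment — the
partial-volume response to slice thickness, kernel sharpness/noise
trade-offs, island formation, smoothing shrinkage, staircase and warping —
under exactly known ground truth. Orderings and qualitative effects
(threshold response, thickness and kernel effects, smoothing-level effects,
printer quality) are meaningful and tested. Absolute deviation magnitudes
are *not* transferable to any scanner, software product or printer: they
derive from stylized PSF/noise parameters and an idealized HU mapping, with
no beam hardening, scatter, tube-physics, infill or extrusion-path
modelling. Likewise the two total-error presets characterize this synthetic
pipeline, not any physical one.

Two resolution limits of the default conditions are worth knowing. First,
0.4 mm and 0.6 mm slices are nearly equivalent once the in-plane grid is
0.5 mm and the soft kernel blurs at 1.2 mm FWHM: their 6σ ΔS values differ
by about the seed-to-seed scatter of the estimator (~0.002 mm), so tests of
the thickness ordering treat that pair as a tie while the 0.6 → 5.0 mm
increase is strict and roughly six-fold. Second, at the optimal threshold
(−400 HU) the mean deviation is within ±0.07 mm of zero for every
thickness — the zero crossing of the threshold response — so orderings of
the *mean* are only resolvable away from the optimum (e.g. at −600 HU the
positive bias grows with thickness).

Problem sizes were chosen so the full default study (210 + 21 + 10 records
with 100,000-sample deviation analyses) completes in a few minutes on one
CPU: phantom complexity 3, in-plane spacing 0.5 mm, and the 16-sub-ray
occupancy model. All are configuration fields, not constants.

## A worked run

```{r}
library(printqa)

cfg <- study_config(seed = 1)
sege <- run_sege_sweep(cfg)
dee  <- run_dee_study(cfg)
pre  <- run_pre_study(cfg)
total <- run_total_error(cfg, sege = sege, dee = dee, pre = pre)

autoplot(sege, metric = "dV_rel_pct")
autoplot(dee, metric = "six_sigma_dS")
autoplot(total)

glance(attr(total, "totals")$config_1_optimal)
```
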