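# printqa

Error propagation along the medical 3D-printing pipeline, simulated end to
end at the desk.

Patient-specific anatomical models are produced by a chain of steps — CT
imaging, threshold segmentation, digital smoothing, 3D printing — and each
step deforms the geometry. Quality assurance needs the error contribution of
each step separately, and a rule for combining them. `printqa` implements
that methodology on fully synthetic data: a femur-like phantom with known
ground truth, a CT simulator (slice thickness, reconstruction kernel,
noise), sub-voxel threshold segmentation, software-like smoothing profiles,
a fused-filament print simulator (layer staircase and bed-adhesion warping),
and an open surface-deviation engine (rigid ICP alignment, exact
closest-point signed distances). It is aimed at people building or teaching
QA for point-of-care 3D printing, and at anyone who needs an open,
deterministic test bed for surface-deviation metrology.

## The error model

Each stage comparison yields signed surface deviations ΔS sampled on the
analyzed surface; negative values mean the analyzed object is smaller than
its reference. A stage is summarized by the mean deviation and the width of
the ±3σ interval (6σ ΔS, ≈ 99.7% coverage under normality). The three
partial errors are

* **SegE** — ground truth vs. direct segmentation result,
* **DEE** — direct segmentation vs. print-STL (after smoothing),
* **PrE** — print-STL vs. printed model,

and they combine by Gaussian error propagation, assuming independent stages:

```
Δmean_Total = Δmean_SegE + Δmean_DEE + Δmean_PrE
σ_Total     = sqrt(σ_SegE² + σ_DEE² + σ_PrE²)
```

Means can cancel each other; the spread only grows with each step.

## A worked example

One segmentation-error measurement, from phantom to deviation statistics:

```r
library(printqa)

phantom <- femur_phantom(complexity = 2, seed = 7)
mesh_volume(phantom)
#> [1] 51998

proto <- ct_protocol(slice_thickness_mm = 1.5, kernel = "soft", seed = 1)
vol <- simulate_ct(phantom, proto)
vol
#> <hu_volume> 69 x 92 x 136 voxels (slice, row, col), spacing 0.50 x 0.50 x 1.50 mm, HU range [-1024, 262]

seg <- segment_threshold(vol, -400, reference_volume_mm3 = mesh_volume(phantom))
seg
#> <segmentation_result> threshold -400 HU, keep_all: 1 component(s), 51755 mm^3, 153604 triangles, included

dev <- signed_surface_deviation(seg$mesh, phantom, n_samples = 2e4, seed = 1)
dev
#> <deviation_stats> n = 20000: mean dS -0.0234 mm, sigma 0.0578 mm, 6-sigma dS 0.3467 mm
```

The segmentation at the optimal threshold (−400 HU, the midpoint between
air at −1000 HU and the object at +200 HU) recovers the 52.0 cm³ phantom to
within 0.5%; at 1.5 mm slices the surface wobbles with a 6σ band of
0.35 mm and sits 0.023 mm inside the truth on average. Feeding this SegE
into the propagation together with a smoothing (DEE) and a printing (PrE)
measurement:

```r
propagate_total(
  partial_error("SegE", dev$mean_dS, dev$sigma),
  partial_error("DEE", -0.007, 0.041),
  partial_error("PrE", -0.005, 0.031))
#> <total_error> -0.0354 mm +/- 0.0773 mm (6-sigma 0.4640 mm)
```

The full study design (5 slice thicknesses × 2 kernels × 7 thresholds,
3 software profiles, 3 smoothing levels, 2 printers × 5 replicates) is
driven by a configuration object:

```r
cfg  <- study_config(seed = 1)
sege <- run_sege_sweep(cfg)   # 210 segmentation records
dee  <- run_dee_study(cfg)    # 21 print-STL records
pre  <- run_pre_study(cfg)    # 10 printed replicates
run_total_error(cfg, sege = sege, dee = dee, pre = pre)
```

Each runner returns a tibble with an `autoplot()` method; excluded cells
(segmentations below the 30,000 mm³ volume cut-off, where alignment is no
longer reliable) appear as gaps in the tables and plots. See the
vignette (`vignettes/error-propagation-pipeline.Rmd`) for the models behind
each stage and their assumptions.

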