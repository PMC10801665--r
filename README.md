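# needletrace

Automatic digitization of interstitial needles for CT-based high-dose-rate
(HDR) brachytherapy planning, with end-to-end geometric and dosimetric
evaluation on synthetic needle phantoms.

In gynecologic interstitial HDR brachytherapy, 3–6 trocar steel needles
(1.5 mm diameter) are implanted freehand and an Ir-192 source is stepped
through them. Planning requires *digitizing* each needle — identifying its
3D trajectory in the planning CT — which is manual, slow and
planner-dependent, and is complicated by 5 mm slices, touching/crossing
needles and metal streak artifacts. This package is for medical-physics
researchers who want a fully inspectable, reproducible implementation of the
deep-learning digitization workflow: every stage from phantom generation to
DVH comparison is open code with seeded determinism and oracle-tested
numerics.

## What is inside

* **Phantom generator** (`make_phantom`) — seeded CT-like volumes at
  clinical voxel geometry (0.8/0.8/5.0 mm) with tubular needles around
  analytic polynomial centerlines, soft-tissue background, optional streak
  artifacts, an HR-CTV and organ-at-risk structures, plus exact ground truth.
* **Segmentation network** (`build_model`, `train_model`, `predict_mask`) —
  a 3D U-Net with optional additive attention gates on the skip connections,

  α = σ₂( ψᵀ σ₁(Wₓᵀx + W_gᵀg↑ + b_xg) + b_ψ ),

  group normalization, and the soft Dice loss
  L = 1 − 2|P∩T| / (|P|+|T|+ε), trained with Adam (lr 5×10⁻⁴, batch 1).
  The network and its backpropagation are implemented natively in
  R/RcppArmadillo — no external deep-learning framework.
* **Digitization** (`digitize_mask`, `sample_dwells`) — 26-connected
  instance labeling, per-slice centroid centerlines, polynomial trajectory
  fits x(z), y(z) with sub-slice tip extrapolation, and arc-length-exact
  dwell placement.
* **Geometric evaluation** (`geo_report`, `paired_t`) — Dice, Jaccard,
  exact Hausdorff distance in mm, needle tip error (length reading) and
  shaft error over optimally matched needle pairs, with paired t tests for
  method comparison.
* **TG-43 dose engine** (`dose_grid`, `compute_dvh`, `compare_plans`) —
  point-source formalism Ḋ(r) = S_K Λ (r₀/r)² g(r) φ_an(r), cumulative DVHs
  with D90 / D100 / D2cc, and manual-vs-automatic plan comparison with dwell
  times held fixed.
* **Pipeline + CLI** (`run_pipeline`, `inst/cli/needletrace.R`) — one seeded
  run from phantom generation to DVH reports with a checksummed manifest;
  shell subcommands `generate`, `train`, `predict`, `digitize`, `evaluate`,
  `dose`, `compare`, `pipeline`.

## Worked example

Digitize the ground-truth mask of a four-needle phantom and measure how much
dose error the digitization chain itself introduces:

```r
library(needletrace)

ph <- make_phantom(phantom_config(n_needles = 4, curvature = 2, seed = 42))
print(ph$volume)
#> <volume3d> 64 x 64 x 16 voxels, spacing 0.8/0.8/5 mm
#>   origin (0.00, 0.00, 0.00) mm, range [-1e+03, 3e+03]

mask <- volume3d((ph$truth$instance_mask$data > 0) * 1.0,
                 ph$volume$spacing, ph$volume$origin)
traj <- digitize_mask(mask)
print(traj[[1]])
#> <trajectory> needle 1: 16 points, degree 3, length 77.58 mm, tip (15.25, 23.38, 77.50)

geo_report(mask, mask, traj, ph$truth$centerlines)
#> <geo_report> DSC 100.0%  JI 100.0%  HD 0.00 mm  tip 0.86 mm  shaft 0.08 mm  (4 needles)

pairs <- pair_trajectories(traj, ph$truth$centerlines)
src <- default_source_model()
plan_of <- function(trajs) brachy_plan(
  lapply(trajs, sample_dwells, step_mm = 2.5, offset_mm = 0, n_dwells = 10),
  prescription_dose_gy = 6, source = src)
compare_plans(plan_of(lapply(pairs, `[[`, "truth")),
              plan_of(lapply(pairs, `[[`, "pred")),
              ph$volume, ph$truth$structures, allow_extrapolation = TRUE)
#>   structure metric manual_gy automatic_gy diff_gy rel_diff
#> 1     hrctv    D90      1.52         1.48  0.0453   0.0298
#> 2     hrctv   D100      1.09         1.06  0.0300   0.0275
#> 3   bladder   D2CC      3.32         3.17  0.1477   0.0445
#> 4    rectum   D2CC      7.40         7.26  0.1400   0.0189
```

Reading the numbers: recovering trajectories from the rasterized mask alone
already carries a tip error of ~0.9 mm (the 5 mm slices quantize the true
tip position) and a shaft error under 0.1 mm; propagating those dwell shifts
through the dose engine moves HR-CTV D90 by ~3%. Network-predicted masks are
evaluated against this same ground truth — see `run_pipeline()` and the
vignette for the full training workflow.

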