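---
title: "Automatic interstitial-needle digitization: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic interstitial-needle digitization: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(needletrace)
```

# The problem

CT-guided high-dose-rate (HDR) interstitial brachytherapy for cervical
cancer steps an Ir-192 source through 3-6 trocar steel needles implanted
freehand into the target. Before planning, each needle's 3D trajectory must
be *digitized* — identified in the planning CT so the planning system knows
where the source can dwell. Manual digitization is slow, planner-dependent
and error-prone: the needles are thin (1.5 mm diameter against 5 mm slices),
often touch or cross, and generate metal streak artifacts. Because the dose
falls off as $1/r^2$ around every dwell, millimeter-scale digitization
errors translate directly into target and organ-at-risk dose changes.

`needletrace` implements the full automatic pipeline: a synthetic phantom
generator with analytic ground truth, an attention-gated 3D U-Net that
segments needle voxels, centerline digitization with polynomial smoothing,
the standard geometric accuracy panel, and a TG-43 point-source dose engine
that quantifies the dosimetric consequence of replacing manual digitization
with the automatic one.

# Segmentation network

The segmenter is a 3D U-Net: per resolution level two $3^3$ convolutions
(zero padding), each followed by group normalization and ReLU; $2\times$
max-pooling between encoder levels; stride-2 transposed convolutions in the
decoder; skip concatenation; and a $1^3$ convolution with sigmoid output.
Channels double per level from `base_channels`. Under the layer-counting
convention adopted here (the double convolutions of every level plus the
up-convolutions, excluding the $1^3$ head), the network has $5\,\mathrm{depth}-3$
convolutional layers; the full-scale topology (`depth = 5`) therefore counts
22, and `count_conv_layers()` documents this.

## Additive attention gates

With attention enabled (the "CNN + AG" variant), each skip connection is
gated before concatenation. For a fine encoder feature map $x$ and the
coarser decoder gating signal $g$:

$$q = \psi^{T}\,\sigma_1\!\left(W_x^{T} x + W_g^{T} g_\uparrow + b_{xg}\right) + b_\psi,
\qquad \alpha = \sigma_2(q),$$

where $\sigma_1$ is ReLU, $\sigma_2$ the sigmoid (restricting the attention
coefficients to $[0,1]$), $W_x$, $W_g$, $\psi$ are $1^3$ convolutions and
$g_\uparrow$ is $g$ resampled to $x$'s grid by trilinear interpolation. The
skip feature is scaled voxelwise by $\alpha$, suppressing responses in
irrelevant regions before the decoder re-reads them. Design points that are
genuinely open in additive-attention architectures, fixed once here:

* **Gate placement** — the gate sits on the encoder feature immediately
  before skip concatenation; the gating signal is the decoder feature at the
  next-coarser level.
* **Resampling side** — the coarse gating signal is trilinearly upsampled
  to the fine grid *before* the additive combination, so $\alpha$ is computed
  directly at the fine resolution; the loop-oracle tests transcribe exactly
  this composition.
* **Intermediate width** — $F_{int} = C_x/2$ (minimum 1), the customary
  additive-attention sizing.
* **Group normalization** — after every $3^3$ convolution with 4 groups by
  default; an encoder-only placement (`gn_encoder_only`) is also provided and
  tested. Group (rather than batch) normalization suits the batch size of 1.

## Loss and training recipe

Training minimizes the soft Dice loss
$$L = 1 - \frac{2\sum p\,t}{\sum p + \sum t + \varepsilon},
\qquad \varepsilon = 10^{-4},$$
which is insensitive to the extreme class imbalance of thin tubes in a large
volume. The optimizer is Adam at learning rate $5\times10^{-4}$, batch size
1, up to 200 epochs at full scale. Augmentation draws one in-plane transform
per sample per epoch — rotation (±15° default), horizontal/vertical flips,
isotropic scaling (0.9-1.1) — applied identically to image and mask
(bilinear vs nearest-neighbour). Rotations are restricted to the slice plane
because needles are near-axial and the downstream digitization is
z-parameterized; the rotation and scale ranges are configuration knobs, not
claims. Volumes are cropped centrally in-plane before the network (512 →
256 clinically; 64 → 32 at this package's test scale) purely for
computational efficiency.

The network, its attention gates, group normalization, the loss and the full
backpropagation are implemented natively (RcppArmadillo im2col/GEMM
convolutions; the convolution GEMMs run in single precision, the customary
training precision, while all surrounding arithmetic is double). Gradients
are verified against central differences in the test suite.

# Synthetic phantom

No patient data ship with the package, so a seeded generator stands in for
the clinical cohort. It emulates the features that make the clinical problem
hard, and its defaults are the package's fixed study conditions:

* grid 64 × 64 × 16 voxels at 0.8 / 0.8 / 5.0 mm (the clinical in-plane
  resolution and slice thickness; the grid is a region of interest around the
  implant rather than a full 512 × 512 matrix, and full-size generation
  remains configurable);
* 3-6 needles (default 4) of 1.5 mm diameter, each a tube around a smooth
  z-monotone curve — per-axis polynomials of degree ≤ 2 with bounded in-plane
  deviation (`curvature`, default 2 mm), matching nearly-straight freehand
  trocar insertions and giving closed-form ground truth;
* a soft-tissue ellipse (noisy ~40 HU) in air, needle cores at 3000 HU;
* the true tip placed a random sub-slice distance above the last slice
  centre, reproducing the tip quantization caused by 5 mm slices;
* optional radial streak artifacts around every needle cross-section, linear
  in their strength parameter, with needle cores never dropping below half
  the core intensity;
* an HR-CTV ellipsoid scaled to enclose ≥ 95% of needle voxels and two
  organ-at-risk ellipsoids (bladder anterior, rectum posterior), mutually
  disjoint;
* a minimum centerline separation knob (default 3 mm; 0 permits the
  touching/crossing configurations that defeat centroid-based digitization).

What the generator does **not** emulate: real CT physics (beam hardening,
photon starvation), anatomical texture, deformation, or the full variability
of clinical implants. Passing tests on phantoms therefore demonstrates that
the pipeline's machinery is correct and self-consistent at clinical voxel
geometry — not that the trained toy models would transfer to patients.
Insertion geometry (template vs freehand angles) is not described for the
clinical cohort; the generator exposes a tilt-angle range (default 0-5° from
the slice normal) rather than fixing one.

# Digitization

Predicted masks are digitized in four steps:

1. **Instance labeling** — 26-connected components, discarding components
   under 5 voxels as noise.
2. **Centerline extraction** — per z-slice unweighted centroid of each
   instance in world mm. Valid because needles are z-monotone in this
   anatomy; it is the simplest method that preserves the z-parameterized
   trajectory contract. An in-plane centroid jump exceeding twice the needle diameter
   between consecutive slices flags the instance as a suspected merge of
   touching needles; flagged needles are excluded from accuracy metrics with
   a warning rather than split, since no splitting procedure is defined.
3. **Trajectory fitting** — least-squares polynomials $x(z)$, $y(z)$
   (degree 3 default, configurable 1-5) in a centered-z basis smooth the
   slice-wise centroid noise; a deliberately low degree enforces the
   smoothing that avoids systematic per-slice error. The tip is the fitted
   point at the deepest mask slice, extrapolated by up to half a slice
   thickness (the scale at which thick slices quantize the true tip); arc
   length comes from fine trapezoid quadrature of the closed-form derivative.
4. **Dwell sampling** — dwells sit at arc lengths `offset + k·step` from the
   tip walking toward the entry point, solved by inverting a cumulative
   arc-length table (resolution well below 0.01 mm). The clinical step size
   and offset are not published; the defaults (2.5 mm, 0 mm) are exposed
   parameters, not assertions.

Predicted and ground-truth needle sets are paired by exact enumeration over
assignments minimizing the total mean in-plane centerline distance (needle
counts are ≤ 6, so exhaustive search is exact and cheap); unmatched extras
are reported as false positives/negatives.

# Geometric metrics

The accuracy panel reports Dice similarity and Jaccard index (as fractions;
percentages in printed reports), exact symmetric Hausdorff distance in
physical mm (anisotropic spacing respected; the exact maximum, not a
percentile), and two trajectory errors over matched pairs:

* **Tip error** — two conventions circulate for the per-needle tip metric
  (tip-point distance vs needle-length difference); the length reading is the
  primary definition here, the mean absolute difference of needle arc lengths
  $\frac{1}{N}\sum_i |\,\mathrm{len}(P_i) - \mathrm{len}(T_i)\,|$, with the
  mean Euclidean tip-to-tip distance reported alongside as a clearly labelled
  secondary diagnostic.
* **Shaft error** — mean in-plane distance $\lVert P(x,y)-T(x,y)\rVert$
  between the fitted curves evaluated at the same z, averaged over the
  slices a pair shares and then over needles (the per-needle point count is
  not constant across needles, so the average is taken per pair as written).

Degenerate inputs are defined rather than left to chance: empty-vs-empty
Dice/Jaccard is 1 with a warning; Hausdorff on an empty mask is an error;
pairs without common slices are dropped with a warning. Per-case method
comparisons use the classic paired t test (two-sided, $n-1$ df), which the
suite cross-checks against an exhaustive sign-flip permutation.

# Dose engine

Dose is recalculated with the 1-D (point-source) TG-43 formalism:
$$\dot D(r) = S_K \,\Lambda \left(\frac{r_0}{r}\right)^2 g(r)\,\phi_{an}(r),
\qquad r_0 = 10\ \mathrm{mm},$$
summed over all dwells weighted by dwell time. The 2-D line-source
formalism is deliberately out of scope: the clinical recalculation lives
inside a commercial planning system, and the point-source form keeps the
engine fully testable against closed forms (inverse-square ratios,
superposition) while preserving exactly what the comparison needs — the
sensitivity of dose metrics to dwell geometry. Radial dose and anisotropy
tables are linearly interpolated inputs; the bundled tables are *generic
synthetic* Ir-192-like curves (clearly labelled, not consensus data for any
commercial source), and unity tables are provided for analytic tests.
Distances are clamped at 0.5 mm near a dwell with a warning, since the
formalism diverges at the source; points beyond the table range raise an
error unless extrapolation (boundary clamping) is explicitly enabled.

DVHs are cumulative, over structure voxels, with 0.01 Gy bins; $D_{90}$,
$D_{100}$ and $D_{2cc}$ invert the binned curve with linear interpolation
(the suite checks them against a full voxel sort to within one bin; $D_{2cc}$
is undefined, with a message, for structures under 2 cm³). The
manual-vs-automatic comparison holds dwell counts and times fixed between
the two plans — only the dwell geometry differs — reporting the signed
difference $D_{manual} - D_{automatic}$ and its relative form.

# Problem sizes and numerical choices

The package's own benchmark conditions, chosen once: phantoms at the
64 × 64 × 16 default; networks of depth 3 with 8 base channels trained 50
epochs on 10 phantoms with 3 held-out, cropped to 32 × 32 in-plane, repeated
over 3 seeds with both variants on identical data. These sizes keep a full
single-CPU run in minutes while preserving the clinical voxel geometry;
depth, channels, grid and epochs all scale up by configuration. Other fixed
numerics: prediction threshold 0.5 (monotone, so any threshold preserves
mask nesting); He-normal initialization; Adam $(\beta_1,\beta_2) =
(0.9, 0.999)$; group-norm $\varepsilon = 10^{-5}$; arc-length tables of 4001
points; dwell inversion by linear interpolation on that table. Every source
of randomness flows from one top-level seed through deterministic stage
seeds, so phantom generation, training, and the full pipeline are exactly
reproducible; reports, plans, a structured log and a checksummed manifest
are written per run.

# Known limitations

* Phantom realism is deliberately limited (see above); reported phantom
  accuracies should not be quoted as clinical performance.
* The centroid centerline assumes z-monotone needles; strongly oblique or
  looping catheters would need a different parameterization.
* Touching-needle merges are flagged and excluded, not resolved.
* Point-source TG-43 ignores source anisotropy along the cable axis
  ($F(r,\theta)$) and the line-source geometry factor.
* The trained models at test scale are toys; no pretrained clinical weights
  are shipped.

# A minimal end-to-end run

```{r example}
library(needletrace)

cfg <- pipeline_config(
  out_dir = "run1",
  n_train = 10, n_val = 3,
  net = net_config(depth = 3, base_channels = 8, use_attention = TRUE),
  train = train_config(max_epochs = 50, crop_size = 32),
  seed = 1)
res <- run_pipeline(cfg, verbose = TRUE)

res$geo[[1]]      # per-case geometric report
res$dvh           # manual-vs-automatic DVH metric differences
```
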