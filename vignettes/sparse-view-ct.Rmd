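---
title: "Sparse-view CT simulation, residual U-Net correction, and reader-study analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view CT methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sparse-view CT reduces radiation dose by acquiring far fewer angular
projections than a standard scan, at the price of characteristic streak
artifacts introduced by filtered backprojection (FBP) from undersampled
data. A residual convolutional network can learn the artifact component —
the difference between a sparse-view and a full-view reconstruction — and
subtract it, restoring diagnostic quality at a fraction of the views.

This package rebuilds that whole study design as tested, seeded code that
runs on synthetic data:

1. **Phantoms** (`generate_phantom`, `generate_cohort`): 2-D chest-CT-like
   slices in Hounsfield units with two lung fields, vessel-like structures,
   and (for diseased subjects) exactly one nodule with an exact binary
   ground-truth mask.
2. **Projection** (`forward_project`, `subsample_views`,
   `fbp_reconstruct`, `make_view_series`): parallel-beam Radon transform to
   a 2,048-view sinogram, uniform angular subsampling to
   16/32/64/128/256/512 views, and Ram-Lak-filtered backprojection.
3. **Preprocessing** (`apply_window`, `make_residual_pair`,
   `apply_residual_correction`, `split_cohort`): lung-window normalization
   (width 1,700 HU, level −600 HU → clip to [−1450, 250] HU, scale to
   [0, 1]), residual labels, and subject-level data splits.
4. **Model and training** (`unet_config`, `build_model`, `train_model`):
   a dual-frame U-Net trained per view count with MSE loss, Adam,
   exponential learning-rate decay and best-validation checkpointing —
   implemented natively (compiled conv/pool/upsample kernels plus
   backpropagation), since no deep-learning framework is assumed.
5. **Evaluation** (`mse`, `ssim`, `summarize_iq`): per-image MSE/SSIM
   against the full-view reference with mean-and-95%-CI aggregation.
6. **Reader study** (`reader_profile`, `simulate_annotations`, `dice`,
   `classify_detection`, `diagnostic_metrics`, `clustered_wilcoxon`):
   simulated radiologists scoring quality/confidence/artifacts and
   segmenting nodules, analysed with the field's observer-study statistics.

## The acquisition model

Projection uses a parallel beam over the half-open interval [0°, 180°),
2,048 evenly spaced angles at full sampling, and a detector row wide enough
to cover the image diagonal (avoiding truncation artifacts that would
confound the streaks). Line integrals are taken with unit pixel steps and
bilinear sampling, so each projection row integrates to the image sum — a
property the tests exercise directly. Sparse views keep every *k*-th angle
starting at 0°, which keeps spacing uniform; the angular anchor is a
convention (the subset is not otherwise determined).

FBP uses the discrete Ram-Lak kernel (value 1/4 at lag zero, −1/(πn)² at
odd lags) evaluated by FFT on zero-padded projections, then backprojects
with linear detector interpolation and the π/(2·n_views) scaling for
uniform angles. Sampling |f| directly would bias the DC term; the
real-space kernel avoids that.

Windowing is applied to reconstructions only. FBP is linear, so the order
would matter only for clipped extremes.

### Fixed-point windowing

`apply_window` snaps normalized images to a 2⁻²⁴ grid (a perturbation
below 6×10⁻⁸, finer than single precision). On that grid the residual
`sparse − full` and the correction `sparse − residual` are exact in double
arithmetic, so a residual round-trip reproduces the full-view image *bit
for bit* — an invariant the pipeline asserts. Without quantization a
handful of pixels per image (those mixing clipped-to-zero values with
wide-exponent neighbours) would differ by 1 ulp.

### Residual sign convention

The training label is defined here as `residual = sparse − full` (the pure
artifact), so the corrected image is `sparse − prediction`. The opposite
convention (`full − sparse`, corrected by addition) is equivalent up to
sign; describing both at once is contradictory, so the package fixes this
one and states it in `make_residual_pair`'s documentation.

## The dual-frame U-Net

The network takes a normalized sparse-view slice and predicts the artifact
image. The contracting path has four encoder blocks (two 3×3 convolutions,
each followed by batch normalization and ReLU), 2×2 max pooling between
blocks, and a two-convolution bottleneck; the expanding path mirrors it
with 2×2 nearest-neighbour upsampling and skip concatenations; a final 1×1
convolution maps back to one channel. The *dual-frame* variant adds a
bridge from each encoder block's pooled output to the input of the
associated decoder block before upsampling; these extra connections follow
the frame-condition construction from the deep convolutional framelets
literature and reduce the blurring of plain U-Nets. `dual_frame = FALSE`
switches the bridges off (a config switch, not a benchmarked comparison).

Convolutions are bias-free (batch norm makes biases redundant); the final
1×1 convolution carries a bias. Initialization is Glorot-uniform with an
exposed seed, except the final convolution, which starts at **zero**: the
untrained model then predicts a zero artifact and the correction starts as
the identity. This residual-head policy is a deliberate deviation from
framework-default initialization — without it, a desk-scale budget (a few
hundred optimizer steps) is spent entirely on shrinking the initial random
output transient rather than learning streaks.

### Parameter accounting

`count_parameters` follows the Keras "total params" convention:
convolution kernels and biases plus batch-norm γ/β and moving statistics.
The canonical configuration (`unet_config_canonical()`: widths
64/128/256/512, bottleneck 512, bridges at every level) counts
**22,728,321** parameters.

The published total for this architecture is 21,971,584. We attempted to
pin the wiring down with that number as the arbiter and failed: an
exhaustive enumeration — encoder widths doubling from bases 8–128, depths
3–6, bottleneck factors 1–2, bias on/off, batch-norm counting conventions
(omitted / trainable-only / total), nearest-neighbour vs transposed-conv
upsampling, bridges concatenated before or after upsampling, one to three
convolutions per decoder block, and a closed-form solve for the bottleneck
width over all width 4-tuples in multiples of 8 — reproduces the printed
number only with wirings that contradict the architecture's description
(for example, bridges at the outermost levels only, or second decoder
convolutions missing at the two middle levels). We therefore keep the
faithful construction and report the honest count; the acceptance test
recording the published value fails by design and the discrepancy is
documented rather than papered over.

## Training

MSE loss; Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷); batch size 6; initial
learning rate 10⁻³ decayed per epoch by `exp(−0.1)` (so
`lr_n = 0.001·e^{−0.1 n}`, verified to 10⁻¹²); at most 30 epochs at full
scale; early stopping when validation loss stops improving (patience is
not fixed by the emulated study; default 5 epochs, configurable, with a
`min_delta` knob); the returned weights are those of the
minimum-validation-loss epoch. One independent model is trained per view
count. Batch-norm running statistics use momentum 0.99 at full scale and
0.9 in the desk configuration — with only ~10² updates, a 0.99 momentum
leaves inference-mode statistics stale and misleadingly inflates
validation loss.

The desk profile (128×128 slices, depth-2 width-8/16 toy model) exists so
the central effect — postprocessed MSE below sparse MSE on held-out
subjects — reproduces in minutes on one CPU. It demonstrates the
mechanism, not the published effect sizes.

## The synthetic world

Phantoms: a soft-tissue thorax ellipse (≈0 HU) on air (−1000 HU), two
−800 HU lung fields, a vertebral body, and per-lung vessel trees drawn as
tapering random walks at soft-tissue density. Diseased slices carry one
soft-edged disk nodule of diameter drawn uniformly from 1.1–1.9 cm
(inside the 1–2 cm inclusion band of the emulated cohort, with margin for
pixelization); the mask is the exact disk support, and its equivalent
diameter is asserted to lie in [1, 2] cm. Pixel spacing defaults to
0.7 mm/px (≈36 cm field of view at 512 px — chest-CT-typical; no spacing
is dictated by the emulated study, so physical sizes are conventions
flagged in `cohort_config`). One slice per subject feeds the reader-study
path; `generate_slice_stack` emulates multi-slice scans for the training
path.

Readers are statistical stand-ins, not image analysts: detection follows a
per-reader logistic model in log₂(views) (defaults fitted to sensitivities
rising from ≈0.45 at 16 views to 1 at ≥128); quality/confidence/artifact
scores threshold latent linear-in-log₂(views) variables with shared
cut-points plus a per-reader leniency shift; segmentations of detected
nodules are translation/scale-jittered copies of the truth (≈1.5 mm
boundary noise, giving Dice ≈0.8–0.9); missed detections are empty or,
with probability 0.25, displaced with zero overlap; healthy images are
falsely marked at rate 0.08. The postprocessing effect is a single
additive latent boost tapered linearly from full strength at 16 views to
zero at 256 — the simplest structure that makes the two arms converge as
views increase, as observed. Because annotations are drawn from this
model rather than from pixels, a green reader-study test validates the
*analytics* (design enumeration, detection classification, Dice rule,
clustered test), not radiologist behaviour.

## Reader-study analytics

* **Dice** uses the zero rule: empty or non-overlapping segmentations
  score 0.
* **Detection classification**: on a diseased subject any mark overlapping
  the truth is TP (with its Dice value); an empty or displaced mark is FN
  — a displaced mark is *only* FN, not FN + FP. On a healthy subject any
  mark is FP, none is TN. The negative class is healthy subjects.
* **Diagnostics**: sensitivity, specificity, F1, NPV; undefined ratios are
  reported as `NA`, never as 0.
* **Clustered Wilcoxon signed-rank** (`clustered_wilcoxon`): zero
  differences dropped (classical convention), absolute differences ranked
  with average ranks, statistic `T = Σ sign·rank`, cluster-robust variance
  `Σ (cluster sums)²` in the Rosner–Glynn–Lee style, asymptotic normal
  p-value. With singleton clusters this is *exactly* the classical
  signed-rank normal approximation, and at the 3-reader × 19-subject
  design its type-I error calibrates into [0.03, 0.07] at α = 0.05 (both
  are acceptance-tested; a within-cluster sign-flip permutation oracle
  agrees with the analytic p to < 0.02). The cluster key defaults to the
  subject — three readers rate the same 19 subjects, and pooling to
  n = 57 makes subject the repeated-measures unit — with reader available
  as an alternative. The alternative is one-sided (processed > sparse;
  for artifact severity the inequality is flipped since lower is better).
* **Score pooling**: condition means over readers × subjects (n = 57 per
  condition in the full design). Dice means count non-TP diseased records
  as zeros by default (`dsc_mode = "tp_zero"`), with `"tp_only"` as the
  alternative, since the published averaging is ambiguous.
* The 512-view level is excluded from the reader-study path (it is
  indistinguishable from full view) but kept in the image-quality path.

## Numerical and design choices not covered above

* Detector count defaults to the smallest odd integer covering the image
  diagonal.
* SSIM uses Gaussian-weighted 11×11 windows (σ = 1.5), K₁ = 0.01,
  K₂ = 0.03, data range 1.0 on normalized images, averaged over the valid
  region; metrics are computed on whole images, not lung ROIs.
* Confidence intervals are Student-t over per-image values; whether the
  published intervals were per image or per subject is unknowable from the
  text, so per-image is used and noted here.
* Splits are seeded and subject-level; the original split is
  irreproducible (unstated seed), so the seed is an explicit config field.
* Post-correction images are clipped to [0, 1] before metrics so SSIM's
  data range stays valid.
* All randomness flows from explicit integer seeds through a deterministic
  per-stage seed-derivation helper; identical configs reproduce cohorts,
  annotations, splits and training runs bit-for-bit (single-threaded
  BLAS assumed for exact training reproducibility).

## Limitations

2-D slices only; parallel beam (no fan/cone geometry, detector physics or
dose model); no photon noise beyond what undersampling creates; phantom
anatomy is geometric, not anatomical; simulated readers cannot validate
human perception; desk-scale training demonstrates direction, not
magnitude, of the published image-quality gains.
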