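---
title: "Methods: an improved 3D feature pyramid network for low-contrast tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an improved 3D feature pyramid network for low-contrast tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gastric and hepatic tumors in CT are hard segmentation targets: lesions
are low contrast against surrounding soft tissue, their boundaries blur
into the background, slice spacing is much coarser than in-plane
resolution (5–8 mm slices against sub-millimetre pixels), and scanners
and protocols vary across centres. `ifpn3d` implements a volumetric
segmentation network built for exactly these conditions, together with
the full evaluation panel used in this field and a synthetic-phantom
data path, so every stage of the method can be exercised and tested on
an ordinary CPU with no external data.

## The network

**Encoder.** A stem convolution followed by three SE-ResNeXt bottleneck
stages. Each stage downsamples by stride `(2, 2)` in-plane and stride 1
on the slice axis: CT volumes have few slices, so the slice axis is
never downsampled anywhere in the network. After the third stage a
dilated residual stage (dilation 2, stride 1) acts as a bridge,
enlarging the receptive field while keeping the resolution of the last
encoder layer, so the deepest two layers share one grid. The encoder
family is configurable (`se_resnext`, `resnext`, `resnet`) for
backbone ablations.

**Pyramid.** 1×1×1 lateral projections bring the three deepest layers
to a common channel count and a top-down pathway adds each level to the
next finer one (nearest-neighbour in-plane upsampling; an identity for
the equal-resolution pair). The pyramid levels `x1, x2, x3` sit at 1/4,
1/8 and 1/8 of the input resolution in-plane.

**Adaptive spatial feature fusion (ASFF).** For each target level, the
other levels are resized to it (trilinear up, max-pool down, identity
across the equal-resolution pair; the slice axis is never resampled).
A small convolutional branch per source level (1×1×1 conv, group norm,
PReLU, 1×1×1 logit) produces one logit map each; the three maps are
concatenated on the channel axis and softmax-normalized **per voxel**,
giving weights in [0, 1] that sum to one at every voxel. The fused
feature is the per-voxel convex combination

$$\hat y^{\,l} = w_1^l \cdot y^{1\to l} + w_2^l \cdot y^{2\to l} + w_3^l \cdot y^{3\to l},$$

so it is always inside the envelope of its inputs — the property the
test suite checks on random tensors.

**Single-level refinement (SLFR).** Per level, the pyramid feature and
its fused counterpart are concatenated and passed through a 1×1×1
conv/GN/PReLU (whose output also serves as the residual skip), two
3×3×3 conv/GN/PReLU layers, and CBAM attention (channel gate from
average- and max-pooled channel statistics through a shared bottleneck;
spatial gate from channel-wise mean/max maps through a convolution),
then the skip is added back.

**Multi-level refinement (MLFR).** The refined level-2 and level-3
features are upsampled to level-1 resolution, concatenated, refined by
the same 1×1×1 + two 3×3×3 stack, recalibrated channel-wise with a
squeeze-and-excitation block, and read out through a 1×1×1 head, a 4×
in-plane trilinear upsampling and a sigmoid, yielding a full-resolution
probability map rather than a naive average of multi-level predictions.

**Deep supervision.** During training two auxiliary heads emit
full-resolution probability maps: one from the resized-and-averaged
SLFR outputs (stage 2), one from the MLFR trunk (stage 3). Inference
returns only the final map. The exact composition of the supervised
stages is a genuinely open design point (the feature flow between the
refinement stages admits several readings); we attach them to the two
latest feature-fusion stages, which keeps every refinement parameter on
a supervised gradient path — the property the test suite asserts.

## The loss

Each supervised signal uses a hybrid of a soft Jaccard loss

$$L_{jac} = 1 - \frac{\sum_i q_i p_i}{\sum_i q_i^2 + \sum_i p_i^2 - \sum_i q_i p_i + \varepsilon}$$

which directly optimizes overlap, and a class-balanced focal loss
(natural log, `p` clamped to `[ε, 1−ε]`)

$$L_{foc} = -\tfrac1n \sum_i \big[\alpha\, q_i (1-p_i)^\gamma \log p_i + (1-\alpha)(1-q_i)\, p_i^\gamma \log(1-p_i)\big]$$

with defaults α = 0.2, γ = 1, combined as
$L = \lambda L_{jac} + \eta L_{foc}$ with λ = 1, η = 0.1. The total
training loss weights the three signals as
$0.8\,L^{(2)} + 0.9\,L^{(3)} + 1.0\,L^{(f)}$. Setting the two auxiliary
weights to zero exactly recovers single-output training. The ε floor
(default 1e-7) is ours: it stabilizes empty-mask batches; published
formulations leave this unstated.

## Evaluation metrics

`overlapMetrics()` reports Dice = 2TP/(2TP+FP+FN), Jaccard index,
precision and recall in percent from voxel-wise counts.
`surfaceMetrics()` extracts surface voxels (foreground with a
6-neighbour background voxel; the grid border counts as background),
computes the exact Euclidean distance transform of each surface, pools
the two directed nearest-surface distance sets, and reports their mean
(ASD) and 95th percentile (95HD, linear-interpolation percentile) in
voxel units. Conventions we had to fix ourselves, since evaluation on
empty masks is rarely specified: two empty masks score 100% on all
overlap metrics; an empty prediction against a non-empty truth scores
0; surface distances are undefined (`NA`, flagged) whenever either mask
is empty. We pool the symmetric distance set rather than averaging the
two directed means; with the pooled convention ASD and 95HD are exactly
symmetric in their arguments. Dataset aggregation reports Mean ± SD
with the sample (n−1) standard deviation.

## Synthetic phantoms

`generatePhantom()` builds the study conditions the network targets: an
ellipsoidal lesion of contrast 40 intensity units over a background of
60, its indicator blurred (σ = 1.5 voxels in-plane, reduced by the
slice-spacing ratio through-plane) so the image boundary is genuinely
ambiguous relative to the crisp mask; a low-frequency cosine bias field
(amplitude 20) mimicking intensity inhomogeneity; Gaussian noise
(SD 15, contrast-to-noise ≈ 2.7); and 5× thicker slices than in-plane
spacing. These defaults were chosen once as a plausible low-contrast CT
surrogate and are not tuned. What the phantoms deliberately do **not**
model: organ anatomy and neighbouring structures of similar intensity,
partial-volume effects at organ interfaces, scanner-specific noise
texture, pathological shape irregularity, and multi-centre protocol
variation. Passing the overfit and pipeline tests therefore
demonstrates that the architecture, losses, gradients and training
loop work as specified — not that the network generalizes to clinical
CT, which requires real multi-centre data.

The preprocessing pipeline mirrors standard practice: percentile
clipping (0.5–99.5 of nonzero voxels — the "foreground" reading of that
convention — then zero-mean/unit-variance), cubic-spline resampling of
the image with nearest-neighbour resampling of the mask (so it stays
strictly binary), fixed-size patch extraction with zero padding, and
flip/90°-rotation/translation augmentation. Rotations are restricted to
90° multiples so augmented masks remain exact; augmentation magnitudes
are declared defaults (±10% translation, p = 0.5 flips).

## Training and inference

Adam (batch size 2, learning rate 0.003) with reduce-on-plateau
scheduling: when the monitored loss fails to improve by 1e-4 for 10
epochs the rate is multiplied by 0.1 (patience and factor are ours; the
plateau rule itself is standard). With a validation set the monitored
loss and the retained best parameters come from it; without one the
training batches themselves are monitored. Five-fold cross-validation
splits come from a seeded shuffle and contiguous partition. Inference
tiles volumes with 50%-overlap sliding windows, averages overlapping
probabilities uniformly and thresholds at 0.5; the whole inference
protocol (overlap, averaging, threshold) is declared here, as it is
typically left unstated.

Everything is driven by explicit seeds: parameter initialization,
phantom generation, augmentation, batch order and fold splits, so a
fixed configuration reproduces its training history bit-for-bit on CPU.

## Scale profiles and numerical choices

Two configuration profiles ship with the package. `fullConfig()` is the
published operating point: 24×256×256 patches, base width 64, 128
pyramid channels, cardinality 32, SE ratio 16, 500 epochs — sized for a
GPU. `deskConfig()` is the package default and the profile all tests
and examples use: 8×64×64 patches, base width 16 (widths 16/32/64/64),
32 pyramid channels, one residual block per stage, cardinality 4, SE
ratio 8, fusion-branch width 8, 20 epochs. The desk profile was sized
so a full training study (a few hundred optimizer steps) completes in
minutes on a single CPU core while exercising every architectural
component at realistic channel/group ratios.

Choices made where the design was genuinely open, and why:

* **Group normalization everywhere** (8 groups, capped by the channel
  count): batch size 2 makes batch statistics unreliable, and the
  fusion branches use GN anyway.
* **Stride `(1, 2)` read as (slice, in-plane)**, i.e. 3D stride
  (2, 2, 1) in x/y/z order: volumes have few slices, so only in-plane
  resolution is sacrificed.
* **Parameter-free fusion resizes**: trilinear up, max-pool down —
  deterministic and parameter-free, so the fusion weights alone learn
  the level arbitration.
* **Pyramid from the three deepest layers** (the levels are indexed
  1–3); layer 0 only feeds the encoder.
* **Dilation in-plane only** in the bridge stage, matching the
  no-slice-downsampling principle.
* **Binarization threshold 0.5** for mask output.
* **Soft-Jaccard denominator** written as
  `Σq² + Σp² − Σqp + ε`, the standard differentiable
  intersection-over-union form.
* **Weight init** Kaiming-normal (fan-in), GN scales 1/shifts 0, PReLU
  slopes 0.25, head biases 0 — so initial probability maps sit near
  0.5 and the Jaccard term has gradient signal from the first step.
* **PReLU inside the SE/CBAM bottlenecks** (matching the activation
  used everywhere else in the network): with very narrow bottlenecks a
  ReLU there can leave all hidden units dead at initialization,
  cutting the excitation weights off from any gradient.

Degenerate inputs are handled explicitly: constant volumes normalize to
zeros rather than dividing by zero; empty masks trigger the metric
conventions above; non-finite values in a training batch or a
non-finite loss abort with a diagnostic rather than training on
garbage.

## Problem sizes used by the tests

Structural and property tests run an extra-small model (base width 8,
16 pyramid channels, 16×16×4 patches) — the contracts they check are
size-independent. The acceptance suite runs the full desk profile: a
64×64×8 end-to-end pass with gradient checks on every parameter, and an
overfit study (4 phantoms, 200 optimizer steps, three fixed seeds,
success = training Dice ≥ 0.90 in at least two) that verifies the whole
optimization path can actually drive the network to segment. Gradient
correctness is established against central finite differences at small
sizes, where the comparison is exact to first order; the convolution,
distance-transform and fusion kernels are checked against naive loop
oracles.

## Known limitations

* CPU-only: the autodiff engine is compact and BLAS-backed but not a
  GPU framework; the full-scale profile is provided for completeness
  and is not practical without one.
* Single-class segmentation (tumor vs background); the two-class
  liver+tumor variant is out of scope.
* Surface distances are reported in voxel units on the grid, matching
  the field's "(voxel)" convention; physical-mm distances would need
  the spacing folded into the distance transform.
* The phantom generator's realism limits, listed above, bound what
  green tests imply about clinical data.
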