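# ifpn3d

Volumetric segmentation of low-contrast tumors in CT with an improved
3D feature pyramid network, implemented end to end in R.

Abdominal tumors in CT are low-contrast objects with ambiguous
boundaries, imaged with thick, anisotropic slices. This package is for
researchers in medical image analysis who want a fully inspectable,
CPU-runnable implementation of a modern multi-scale segmentation
architecture — every layer, loss and metric is ordinary R (with C++
kernels for convolution, pooling and distance transforms), trainable
and testable without a GPU or any external dataset.

## The method

The network is a three-stage **SE-ResNeXt encoder** (grouped
convolutions with squeeze-and-excitation recalibration) that
downsamples only in-plane — CT volumes have few slices — plus a
**dilated bridge** stage, merged by a top-down pathway into a feature
pyramid `x¹, x², x³` at 1/4, 1/8, 1/8 of the input resolution. Three
mechanisms refine the pyramid:

- **ASFF (adaptive spatial feature fusion).** All levels are resized to
  a target level and combined per voxel with learned softmax weights:

  ŷˡ = w₁ˡ·y¹→ˡ + w₂ˡ·y²→ˡ + w₃ˡ·y³→ˡ,  wₘˡ ∈ [0,1], Σₘ wₘˡ = 1,

  a per-voxel convex combination, so fused features never leave the
  envelope of their inputs.
- **SLFR (single-level feature refinement).** Per level: concatenate
  the features before/after fusion, refine with a 1×1×1 + two 3×3×3
  conv/GN/PReLU layers, gate with CBAM (channel then spatial
  attention), add a residual skip.
- **MLFR (multi-level feature refinement).** Upsample, concatenate and
  refine all three levels, recalibrate with an SE block, and read out a
  full-resolution probability map.

Training minimizes a **stage-wise deeply supervised hybrid loss**: for
each supervised signal, `L = λ·L_jaccard + η·L_focal` (soft Jaccard
`1 − Σqp / (Σq² + Σp² − Σqp)`; focal with balance α = 0.2 and focusing
γ = 1; λ = 1, η = 0.1), summed over two auxiliary heads and the final
output with weights {0.8, 0.9, 1.0}. Evaluation uses the field's
six-metric panel: Dice, Jaccard index, precision, recall (percent) and
ASD / 95HD surface distances (voxels, exact Euclidean distance
transform).

Because the clinical multi-center CT data underlying this line of work
is not public, the package ships a **synthetic phantom generator**
(low-contrast ellipsoid lesions, blurred boundaries, bias field, noise,
anisotropic slices) and uses it for all tests, plus the standard
preprocessing (percentile clipping, cubic-spline resampling,
patching, flip/rotation/translation augmentation), five-fold
cross-validation, Adam with reduce-on-plateau, and sliding-window
inference.

## Worked example

```r
library(ifpn3d)

# four phantom volumes, normalized
pairs <- lapply(1:4, function(i) {
  p <- generatePhantom(phantomSpec(seed = i))
  volumePair(normalizeIntensity(volumeImage(p)), volumeMask(p), volumeSpacing(p))
})
pairs[[1]]
#> VolumePair 64 x 64 x 8, spacing 1 x 1 x 5 mm, 1824 foreground voxels

# train the desk-scale model (a few minutes on one CPU core)
cfg <- deskConfig()
cfg$train$seed <- 101L
res <- trainModel(pairs, cfg, epochs = 100)
tail(res$history, 1)
#>     epoch    lr train_loss   val_loss  val_dice
#> 100   100 3e-04 0.07071344 0.07071344 0.9926555

# segment one volume and score it
pred <- predictVolume(res$model, volumeImage(pairs[[1]]))
evaluatePair(pred$mask, volumeMask(pairs[[1]]), id = "phantom-1")
#> MetricsReport [phantom-1] Dice 99.3%  JI 98.7%  Pre 99.4%  Recall 99.3%  ASD 0.02 vox  95HD 0.00 vox
```

The history shows the hybrid loss falling and the training Dice
reaching ~0.99 as the model overfits the four phantoms — the package's
built-in check that architecture, gradients and optimizer all work.
The final report reads: near-perfect voxel overlap (Dice/JI), equal
precision and recall (no over- or under-segmentation bias), and
surface errors far below one voxel.

A command-line front end wrapping the same functions is installed at
`inst/cli/ifpn3d.R` (`synth`, `train`, `predict`, `evaluate`
subcommands, NIfTI in/out, CSV reports).

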