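---
title: "Coarse-to-fine volumetric segmentation: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine volumetric segmentation: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vbcascade)
```

## The problem and the model

Delineating organs-at-risk (OARs) and target volumes on planning CT is the
bottleneck of radiotherapy planning. The approach implemented here splits
segmentation into two resolution regimes:

1. a **coarse stage** working on the image resampled to a large isotropic
   spacing (default 5×5×5 mm) whose only job is to *localize* the structure —
   its argmax segmentation is reduced to a bounding box, expanded by a
   physical margin and mapped back to the raw grid;
2. a **fine stage** working at small spacing (default 1×1×1 mm) on the crop
   inside that box, which delineates the actual boundary.

The cascade buys three things: most of the volume is never touched at fine
resolution (speed, memory); false positives far from the structure are
*structurally impossible*, because the fine mask is pasted into a zero
canvas inside the box; and the fine model sees a consistent, centred field
of view. Both stages use the same network family.

### VB-Net

The backbone is a V-Net-style 3D encoder–decoder. A spec with `levels = L`
has L stride-2 down-sampling convolutions (kernel 2), doubling channels per
level (capped at 16× the base width), and a mirror decoder of stride-2
transposed convolutions with concatenation skip connections at every
resolution level. Each down/up block carries a configurable number of
**bottleneck residual units**: 1×1×1 channel-halving convolution → 3×3×3
spatial convolution → 1×1×1 restore, added back to the block input. The
bottleneck is what distinguishes VB-Net from plain V-Net: it cuts the cost
of the spatial convolutions roughly fourfold at equal depth. Every
convolution except the final 1×1×1 classifier is followed by instance
normalization and ReLU — instance rather than batch statistics because the
recommended batch size is as small as 2 patches.

The **adaptive input module** (for large structures such as whole-body
skin) prepends a *learned* stride-2 convolution and appends a stride-2
transposed convolution. External shapes are unchanged; the backbone sees
half-resolution data, so its receptive field in input voxels doubles.
Patch sides must be divisible by `2^L` (`2^(L+1)` with the adaptive pair);
the widely used 96³ patch satisfies this for L ≤ 5, whereas the published
large-organ patch 196³ does not — 192³ is the nearest valid size and the
package enforces divisibility at the forward pass.

Channel widths, kernel sizes and level counts of the original network are
not public; the defaults here (base 8, levels 3, one bottleneck per block)
are declared package choices, and every experiment in the tests states its
own (smaller) spec.

### The multi-dimensional adaptive Dice loss

Soft Dice in 3D over the patch is combined with per-slice 2D Dice terms
along the superior–inferior axis:

$$\mathrm{loss}_{\mathrm{adaptive}} \;=\; \lambda_1\,\mathrm{loss}_{3D}
\;+\; \lambda_2 \sum_{i=1}^{n} \lambda^{i}_{\mathrm{adaptive}}\,
\mathrm{loss}^{i}_{2D},
\qquad \lambda^{i}_{\mathrm{adaptive}} = 1 - (d_i)^2,$$

where $d_i$ is slice *i*'s Dice coefficient of the current prediction,
$\mathrm{loss} = 1 - d$ in both dimensions, and $\lambda_1 = 0.7$,
$\lambda_2 = 0.3$. Perfect slices get weight 0 and fully failed slices
weight 1, which concentrates the 2D terms exactly where target volumes
tend to fail: the upper and lower boundary slices.

Numerical choices (the published equations are given without smoothing):

* every Dice form adds `smoothEps` (default 1e-5) to numerator and
  denominator; an empty prediction against an empty slice then scores 0
  rather than NaN, so vacuous slices are neither rewarded nor punished;
* the slice weights $\lambda^i$ are treated as *constants of the current
  prediction* — no gradient flows through them — so each optimization step
  minimizes a fixed convex combination of slice losses. The gradient
  checks in the acceptance suite therefore evaluate the frozen-weight
  objective (`adaptiveLoss(..., sliceWeights = w)`), which is the function
  the optimizer actually descends;
* the slice terms are summed, as printed; an `averageSlices` switch exists
  but is off by default;
* boundary Dice is published by name only. It is implemented as Dice
  masked to the morphological boundary band of the target (dilation minus
  erosion with a 3×3×3 box element, width `boundaryWidthVox`, default 2) —
  a declared interpretation, flagged as such.

All losses consume probabilities; the network outputs raw scores and the
softmax sits at the API boundary (`predictProbs()`), with the analytic
softmax Jacobian applied in score space during training. Every loss has a
hand-derived gradient validated against central finite differences to
1e-4 relative error.

## Training procedure

Patches are sampled per case: **global sampling** draws centres uniformly
over image foreground (normalized intensity above a floor, default −0.9),
**mask sampling** uniformly over labelled voxels; the recommended split is
global→coarse (the localizer must see background context) and mask→fine.
`"mixed"` does 50/50. Patches are augmented jointly (rotation about the
slice axis ±10°, isotropic scale 0.9–1.1, axis flips, integer shifts ±5
voxels; image-only Gaussian noise, SD 0.02) — label channels always with
nearest-neighbour resampling so no fractional labels appear.

The optimizer is Adam with betas (0.9, 0.999) and decoupled weight decay
1e-4 applied to convolution weights only (the published "momentum = 0.9,
decay = 1e-4" is read this way: Adam has no separate momentum, and a
learning-rate decay would conflict with the step schedule that is
specified alongside). The step schedule multiplies the learning rate by
0.1 every 250 epochs (the published setting names only the initial value,
1e-4). An *epoch* is defined as `batchesPerCase` sampled mini-batches per
training case (default 4), since patch sampling has no natural epoch.

Validation uses 10% of the cases; the validation loss is computed at each
epoch end on a **fixed set of mask-centred patches** drawn once before
training (otherwise sampling noise would make early stopping ill-posed).
Training stops after `patienceEpochs = 5` consecutive epochs without a
strict improvement (tolerance 1e-6) of the validation loss, and the
best-validation parameters are kept. Whether the published convergence
rule watches training or validation loss is ambiguous; validation loss is
implemented, matching the sentence describing the validation split.

With all seeds fixed the entire pipeline — phantom generation, training,
inference — is bit-reproducible in single-threaded mode; this is asserted
in the test suite.

## The phantom world

The generator emulates the segmentation setting at desk scale: an
air-analog background (−1000), a soft-tissue body ellipsoid (mean 40), and
K organ ellipsoids (means 100–300, default one organ at 200) with additive
Gaussian noise (SD 10, a plausible CT noise floor), on a 64³ grid at 1 mm.
Ellipsoids were chosen over meshes because closed-form membership gives
analytic oracles: voxel counts vs. ellipsoid volume, exact bounding boxes,
containment checks. Overlapping organs resolve by list order (later wins),
deterministically. Intensities exercise the default CT window (level 40,
width 400) exactly as a real soft-tissue window would.

What a green test does **not** establish: phantoms have sharp ellipsoidal
boundaries, a single intensity per structure, no partial-volume gradients,
no anatomy-dependent context, and no inter-observer label noise. Passing
the end-to-end phantom experiment demonstrates that the machinery —
sampling, losses, backprop, cascade plumbing — is correct, not that the
tiny networks would contour clinical CT. Clinical-grade accuracy requires
tens of thousands of curated cases and GPU-scale training, which is out of
scope here; no test asserts clinical numbers.

## Desk-scale hyperparameters

The package defaults are the recommended clinical-scale settings (patch
96³, lr 1e-4, up to 1000 epochs, patience 5). The tests and the acceptance
script instead train networks of base width 4 with 16³–32³ patches at lr
1e-2 for ~10 epochs: on the noiseless-contrast phantom task this converges
to Dice ≈ 1 in minutes on one CPU, where the clinical defaults would take
hours without changing the outcome. These are configuration values the
framework explicitly leaves open per task; the defaults themselves are
untouched.

In the cascade-vs-single-stage comparison, "equal patch budget" means: the
identical trained fine model, identical patch size and overlap, swept over
the whole image rather than the localized box, with identical
post-processing. The cascade's advantage on phantoms comes from the
structural suppression of far-field false positives plus the mask-sampled
fine model never having seen distant background.

## Inference configuration

Sliding-window prediction tiles the (padded) volume with the training
patch size and a configurable overlap fraction; per-voxel class
probabilities are averaged uniformly over covering windows (no Gaussian
window weighting — the simplest contract, and exact for the phantom task).
Images smaller than a patch are padded (image channel at −1, attention
channels at 0) and cropped back.

Stage resampling follows the recommended table: nearest-neighbour into the
coarse grid; linear for isotropic inputs (nearest for anisotropic) into
the fine grid; predicted masks return to raw spacing by nearest-neighbour
onto the exact box shape, so crop/paste round-trips are shape-safe.
0-based, half-open bounding boxes compose cleanly with crop and paste; the
box margin is specified in mm and converted per-axis with `ceiling`.

If the coarse stage misses the structure entirely, the default behaviour
is a logged fallback to the whole-image box (clinical-style robustness);
`strictCoarse = TRUE` turns this into an error.

**Attention channels** for target-volume work: the OAR-aware map is the
binary union of supplied OAR masks on the fine crop grid (whether the
original is binary or probabilistic is not public; binary union is
implemented, and the mask subset is caller-selectable), and the
boundary-aware map encodes the coarse target's superior–inferior extent as
a per-slice indicator — the minimal faithful encoding of "generated from
the coarse-level target bounding box" given its stated purpose of
preventing upper/lower boundary failures. Both concatenate channel-wise
with the raw crop, and the fine model must have been built with matching
`inChannels` (checked before any compute).

**Post-processing**: per label, either keep the largest 26-connected
component (organ tasks) or remove components below `minCCVoxels` (tumour
tasks; default 27 ≈ a 3 mm cube at 1 mm). Ties for the largest component
break deterministically to the first in scan order. The operation never
adds voxels and is idempotent.

## Known limitations

* Axis-aligned geometry only: no direction cosines, no DICOM series or
  RT structure sets; oblique NIfTI volumes are rejected at read time.
* The NIfTI-1 reader/writer is minimal (single-file, 3D, common dtypes)
  by design; it is not a general neuroimaging I/O layer.
* Single-threaded CPU training only; no mixed precision, no multi-GPU.
* Output-shape rounding under resampling uses R's `round` (half-to-even);
  the convention is asserted by the index-map oracle tests.
* JSON configuration only (no YAML parser in the dependency set).
* The per-slice loss terms assume the slice axis is the third array axis
  by default; configure `sliceAxis` for differently ordered volumes.
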