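---
title: "Patch-based retinal vessel segmentation with a dense U-net: models and methods"
author: "DenseVessel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based retinal vessel segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal blood vessels in a fundus photograph are thin curvilinear
structures — often one to a few pixels wide — whose morphology carries
diagnostic information for diabetic retinopathy, hypertension and other
vascular disease. Segmenting them is a per-pixel binary classification
problem with two characteristic difficulties: the classes are heavily
imbalanced (vessels occupy roughly 10% of the field of view), and the
finest vessels sit at the resolution limit of the image. `DenseVessel`
implements a patch-based convolutional approach to this problem: training
on small crops, densely connected convolutions to preserve fine features,
a dice-overlap loss robust to class imbalance, and overlapping-tile
inference stitched back by frequency-weighted averaging.

## The workflow

A dataset is a collection of *triplets*: a color fundus image, an
expert-drawn binary vessel map (ground truth), and a binary field-of-view
(FOV) mask marking the circular retinal area of the photograph
(`ImageTriplet`).

**Preprocessing.** Color images are collapsed to grayscale — by default
the BT.601 luminance mix `0.299 R + 0.587 G + 0.114 B`; green-channel
extraction, common in retinal work because vessel contrast is strongest in
green, is available as an option. Intensities are treated as floats in
`[0, 255]` regardless of on-disk bit depth. Images are standardized with
*dataset-level* moments: the mean and population (divide-by-N) standard
deviation pooled over every pixel of every training image
(`computeDatasetStats`). The statistics are computed once on the training
split, persisted with the checkpoint, and re-used verbatim for test
images, so train and test pass through the identical transform. Per-image
or sample-variance alternatives were considered and rejected: the pooled
global form is the natural reading of "moments of all training images",
and the choice only rescales the input layer.

**Random patch sampling.** Training patches (default 48 × 48) are drawn by
rejection sampling: a candidate center is drawn uniformly, accepted if it
lies inside the FOV mask, and the patch pair (image, ground truth) is
cropped around it. Two boundary decisions are deliberate. First, centers
are additionally clamped so the patch lies fully inside the image — a
patch centered near the border would otherwise overrun the image, and no
padding semantics are defined for that case. Second, duplicate centers are
allowed; with tens of thousands of draws over a large FOV the duplication
rate is negligible and rejecting duplicates would bias the spatial
distribution. The rejection loop is capped at 10 000 draws per requested
patch; exceeding the cap (possible only with a pathological FOV) is an
error rather than a silent shortfall. A total patch budget is split
equally across training images, flooring with a warning when not
divisible.

**Overlapping-tile inference.** A test image of size `H × W` is covered by
patches whose top-left corners step by a stride (default 5 px), giving
`(floor((H - patch)/stride) + 1) × (floor((W - patch)/stride) + 1)` tiles
in raster order (rows outer, columns inner). Every tile is predicted by
the network; predictions are accumulated into a per-pixel probability sum
(`fullPro`) and visit count (`fullSum`), and the final probability map is
their ratio. Because the tile grid uses floor arithmetic, a right/bottom
margin of up to `stride - 1` pixels can be visited by no tile; those
pixels get probability 0 and are flagged in a coverage mask rather than
invented. An optional reflect-padding mode (`padToCover`) tiles the full
image when that margin matters. Accumulation is done in double precision,
which is what makes the reconstruction-identity property (cropping a known
map and reassembling it reproduces the map to 1e-6) hold tightly.

## The network

The segmentation model is a densely connected U-net operating on
single-channel 48 × 48 patches and emitting a per-pixel vessel probability
of the same size.

*Dense block.* A block of `l` composite layers, each
BN → ReLU → 3 × 3 convolution (+ dropout), where layer `i` consumes the
concatenation of the block input and all previous layers' outputs —
`k0 + (i-1)·k` channels — and produces `k` new feature maps (`k` is the
growth rate). The block output concatenates input and all layer outputs:
`k0 + l·k` channels. Note one wrinkle in the published description of this
architecture family: prose summaries sometimes give the output width as
`k0 + k·(l−1)`, which contradicts the concatenation recurrence itself;
this package follows the recurrence (the standard DenseNet count,
`k0 + l·k`), and `denseBlockSpec()` exposes the analytic trace so tests
can hold the built model to it.

*Topology.* A 3 × 3 stem convolution produces `initChannels` maps; each of
`nDenseBlocks` contracting stages is a dense block followed by a
transition down (BN → ReLU → 1 × 1 convolution halving the channels → 2 × 2
average pooling); a bottleneck dense block sits at the coarsest
resolution; each expansive stage is a transition up followed by
concatenation with the matching contracting block's output (the skip) and
a dense block; a 1 × 1 convolution plus sigmoid forms the head.

*Defaults and why.* Growth rate 16, two dense blocks per path, five layers
per block, and 48 × 48 patches are the standard training configuration for
this architecture on fundus benchmarks, and SGD uses learning rate 0.01
with momentum 0.9 for the published 150-epoch schedule (the phantom
experiments below use far fewer epochs). Three structural details are
package decisions where the architecture description is silent:

* **Stem width** `initChannels = 8`. The stem width is not specified by
  the architecture; dense connectivity means the final expansive block
  already sees ~200 input channels at full resolution, and a narrow stem
  keeps the model (~430 k parameters) trainable in minutes on a single CPU
  core without touching any stated hyper-parameter.
* **Transition up** carries only the `l·k` feature maps newly produced by
  the preceding dense block (the convention of fully convolutional
  DenseNets), 2 × 2 bilinearly upsampled and passed through a
  channel-halving 1 × 1 convolution. Upsampling the full concatenation
  instead would double the expansive path's width at every stage (feature
  explosion) with no described benefit; nearest-neighbor upsampling is
  available via `upsampleMode`.
* **Dropout 0.2** inside dense-block layers (the composite-layer
  definition includes dropout but no rate) and **transition-down
  compression 0.5** (the DenseNet-BC convention; the transition's 1 × 1
  channel count is otherwise unstated).

The plain U-net baseline (`buildUnet`) uses two conv-BN-ReLU layers per
resolution, max pooling, and the same skip/upsample conventions; the
depth-3 default mirrors the comparison setting in which both models are
built with approximately equal trainable-parameter counts.
`matchUnetParameters()` automates that parity search over the baseline's
base width (within 10% by construction of the search grid).

*Numerics.* Weights are He-uniform initialized from R's seeded RNG.
Training runs in single precision through fused BN+ReLU+convolution
kernels (BLAS `sgemm` on a zero-padded buffer, one shifted gemm per kernel
tap); batch norm uses eps 1e-5, biased batch variance, and running-moment
momentum 0.1 for inference. A double-precision reference implementation of
every layer is kept in the package and cross-checked against the float
path in the tests, and all gradients are validated against central finite
differences.

## The loss

The dice coefficient `D = 2 Σ p g / (Σ p² + Σ g²)` measures overlap
between the predicted probabilities `p` and binary ground truth `g`
jointly over all pixels of a batch, and the training loss is `1 − D` with
the analytic gradient

```
dD/dp_j = 2 [ g_j (Σ p² + Σ g²) − 2 p_j (Σ p g) ] / (Σ p² + Σ g²)²
```

Two conventions are ours. A smoothing constant `eps = 1e-6` is added to
numerator and denominator, defining the all-background batch as `D = 1`
and stabilizing the gradient when activity is low. And the batch is pooled
(one `D` over all pixels) rather than averaged per patch: the coefficient
is defined by single sums over labeled pixels, and per-patch averaging
would re-weight patches by their vessel content. A plain per-pixel binary
cross-entropy is provided as the alternative loss (`lossKind`). Because a
vessel-free batch contributes a vanishing dice gradient, mini-batches
(default size 16, chosen for CPU cache behavior; configurable) are
shuffled each epoch so vessel-bearing patches are well mixed.

Training holds out a validation fraction (default 10%) of the patch pairs
by a seeded split, tracks per-epoch training loss, validation loss and
validation dice, and retains the weights of the best-validation-dice
epoch. Model selection by that split is a package choice; the 10% split
itself follows standard practice for this task.

## Elastic augmentation

The offline augmentation doubles the patch set: each patch pair gets one
warped copy. The displacement field starts as per-pixel uniform draws in
`[−1, 1]` in each axis, is smoothed by a Gaussian of scale `sigma` (kernel
support capped at the patch size) and scaled by an amplitude `alpha` in
pixels. Defaults `sigma = 4`, `alpha = 8` are typical elastic-distortion
values for 48 × 48 crops: large enough to bend vessels visibly, small
enough that the warp stays diffeomorphic-like and roughly mass-preserving
(the tests assert the warped vessel fraction stays within ±30% of the
original across 100 seeds). Intensities are resampled bilinearly; labels
use nearest-neighbor so the ground truth stays strictly binary without any
re-thresholding step; out-of-bounds samples replicate the edge.

## Evaluation

All reported metrics are restricted to the FOV mask — the convention of
fundus benchmarks, where the black area outside the retina would otherwise
inflate specificity and accuracy (an all-pixels escape hatch exists in the
CLI). Probability maps are binarized at 0.5 by default (`>=` convention);
Otsu's method is offered as an automatic alternative. Sensitivity,
specificity and accuracy come from the masked confusion counts; degenerate
denominators yield `NA` with a warning instead of a fabricated value. AUC
is computed by the exact tie-aware rank (Mann–Whitney) formulation, which
equals the trapezoidal area under the ROC curve over all distinct
thresholds — so the O(n²) pairwise oracle in the tests is an equality
check to 1e-12, not an approximation.

## The phantom generator

The synthetic module exists so the whole pipeline is testable and
demonstrable with no external download. A phantom triplet emulates the
structure the segmentation problem cares about: a circular FOV; a
branching vessel tree drawn as a random walk with per-step heading jitter
(sd 0.12 rad), stochastic bifurcation (default probability 0.04 per step),
and distal width tapering within 1–4 px — the scale of real retinal
vessels; a source image rendered as a smooth background gradient plus the
signed vessel contrast (dark-on-bright by default, the fundus convention)
blurred at sigma 0.7 px, with Gaussian pixel noise (sd 8) and fundus-like
RGB weighting. Tree growth stops when a per-image vessel-fraction target
drawn from 8–14% of the FOV is reached, and generation fails loudly if the
fraction leaves the 5–20% band bracketing the ~10% vessel prevalence of
real images. Defaults are 128 × 128 images so that desk-scale experiments
run in minutes; the size is configurable up to fundus-benchmark
dimensions.

What phantoms do *not* emulate: the optic disc and macula, central vessel
reflex, lesions and exudates, inter-image illumination variation, and JPEG
artifacts. Passing the end-to-end phantom experiment therefore
demonstrates that the implementation learns and reconstructs curvilinear
structure correctly — it does not certify clinical performance on real
fundus images, which additionally requires the DRIVE/STARE-style training
procedure the `drive` dataset layout supports.

## Problem sizes in the shipped experiments

The package's standard end-to-end experiment — used by the acceptance
script and the heaviest test — simulates 12 phantoms, trains on ~500
patches (55 per training image after equal division) for 15 epochs, and
predicts the 3 held-out phantoms with stride-5 tiling (289 tiles per
image). These sizes are the package's chosen desk-scale study condition:
large enough that the dense U-net must genuinely learn vessel geometry
(validation dice ≥ 0.85 and masked AUC ≥ 0.95 are the pass bars), small
enough to run on one CPU core in minutes. The determinism check reruns a
reduced pipeline (4 phantoms, 60 patches, 2 epochs) twice and requires
bit-identical metric reports; determinism at the small scale implies it at
the large one because every stage draws from per-stage substreams of the
master seed.

## Known limitations

* Training is CPU-bound R/C++ with BLAS; it is meant for desk-scale
  experiments and method study, not for training on full fundus
  benchmarks at 40 000 patches × 150 epochs (hours, as any CPU
  implementation would be).
* Single-channel input only; multi-channel (e.g., RGB) stems would be a
  small extension but are not described by the architecture this package
  implements.
* The floor-tiling margin is reported as uncovered rather than predicted;
  use `padToCover` or a stride that divides the image if full coverage is
  required.
* GIF masks (used by some DRIVE mirrors) are not readable here; convert to
  PNG/TIFF first. PNG, TIFF, JPEG and PGM/PPM are supported.
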