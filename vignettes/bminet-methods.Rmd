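---
title: "Predicting body mass index from structural brain volumes: model, training and localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting body mass index from structural brain volumes: model, training and localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bminet)
```

## The problem

Body mass index (BMI, weight in kilograms divided by squared height in
meters) is linked to brain structure in ways that conventional
region-of-interest analyses describe only partially.  An alternative is
to *predict* BMI directly from a T1-weighted structural MR volume with a
convolutional network and then ask, per voxel, which parts of the image
drove the prediction.  `bminet` implements that workflow end to end for
volumes registered to a common space (e.g. MNI152, downsampled to
91 × 109 × 91 at 2 mm): a 3D separable-convolution regression network
with age/sex covariate fusion, its training protocol, and a
regression-adapted 3D Grad-CAM that yields per-subject and cohort-average
localization maps.

Real cohorts of this kind (large biobank samples) are access-restricted,
so the package also ships a phantom generator that plants a known,
spatially localized, linearly target-coupled signal in synthetic volumes.
Everything downstream — training, evaluation, localization, thresholding
— can then be validated against ground truth.

## The network

The backbone is a cascade of eight convolution blocks.  A block with
kernel extent $N$ and channels $c_{in} \to c_{out}$ applies three chained
*asymmetric* convolutions with kernels $N\times1\times1$,
$1\times N\times1$ and $1\times1\times N$ (stride 1, SAME zero padding,
each with a bias), one batch-normalization stage over the block's
output channels, and a ReLU.  This spatial separability replaces the
$N^3$ factor of a full 3D kernel by $3N$, which is what makes a
231k-parameter 8-block network possible.  The extents are 5 for the
first block and 3 afterwards; the filter count starts at 8 and doubles
entering blocks 2, 4, 6 and 8 (8, 16, 16, 32, 32, 64, 64, 128).  SAME
max pooling (window 3, stride 2) follows blocks 2, 4 and 6.  Global
average pooling (GAP) reduces the 128 final feature maps to a vector;
age (years) and sex (0/1) are appended raw; a fully connected 128-unit
ReLU stage with dropout 0.4 feeds a single linear output unit — the
predicted BMI.

### Parameter accounting

The configuration is pinned down by its parameter counts.  Per block,
trainable parameters are $N c_{in} c_{out} + 2 N c_{out}^2$ convolution
weights, $3c_{out}$ biases and $2c_{out}$ batch-norm scale/shift terms;
each block also carries $2c_{out}$ non-trainable running statistics.
Summed over the eight blocks this gives 214,064; the hidden stage adds
$130 \times 128 + 128 = 16{,}768$ (130 = 128 pooled features + 2
covariates) and the output unit $128 + 1 = 129$: **230,961 trainable**,
plus $2 \times 360 = 720$ running statistics = **231,681 total**.
`count_parameters()` reproduces both numbers exactly, and the test suite
asserts them.  Three structural choices are *forced* by this arithmetic
and are therefore part of the design: biases on all three asymmetric
convolutions (a bias-free build falls 1,080 short), one
batch-normalization stage per block rather than per convolution
(non-trainable count 720 = 2 × 360 channels), and the specific doubling
schedule above.  Two choices are *not* identifiable from the counts and
are recorded here as the package's reading: no activation between the
three asymmetric convolutions within a block (the cascade is treated as
a factored linear convolution), and SAME-style boundary handling for
pooling (output length $\lceil n/2 \rceil$).

### Numerical engine

No deep-learning framework is used: forward, backward and Adam are
implemented in the package (RcppArmadillo).  Activations are stored
channels-first and each asymmetric convolution is one small-by-wide GEMM
over a shifted stack, the cache-friendly orientation for single-CPU
BLAS.  The engine is templated on precision: float64 for oracle and
gradient-check work, float32 (default for `train()`) for the large
seeded runs, which are memory-bandwidth-bound and run about twice as
fast.  Backpropagation is verified against central finite differences on
toy configurations (relative error below 1e-4 in the tests).

Batch normalization uses variance floor `bn_eps = 1e-3` (the
TensorFlow-lineage convention) and running-statistic momentum 0.6.
Neither value is part of the published protocol.  The momentum was set
below the common 0.9–0.99 range deliberately: evaluation-mode outputs
use the running statistics, and with only ~20 optimizer steps per epoch
a long averaging window (1/(1−momentum) batches) leaves the statistics
describing parameters many steps stale, which biases every
evaluation-mode prediction by a common offset while parameters are
still moving quickly.  A window of ~2.5 batches keeps the end-of-epoch
validation pass consistent with the current parameters; at biobank
scale (thousands of steps per epoch) the choice is immaterial.  Batch
means and variances are accumulated in two passes (`E[(x-m)^2]`, never
`E[x^2]-m^2`, which cancels catastrophically in float32 when activation
means dominate their spread).  Both values are `net_config()` fields.

## Training protocol

`train()` follows the published recipe: mean-squared-error loss, Adam
(learning rate 5e-4, $\beta_1$ 0.9, $\beta_2$ 0.999, epsilon 1e-8 — the
framework-default convention, recorded, not published), batch size 8,
Xavier/Glorot uniform weight initialization, batch-norm scale/shift
initialized to 1/0, fully connected biases to 0.01, dropout 0.4 on the
hidden stage during training only.  The training set is reshuffled every
epoch; validation MAE is computed after every epoch in evaluation mode;
the parameter snapshot with minimal validation MAE (earliest epoch on
ties) is restored as the final model.  The last incomplete batch of an
epoch is used, not dropped (the protocol source is silent; this choice
is recorded because batch-norm statistics differ with batch size).

Reproducibility: shuffling, dropout masks and augmentation draws come
from three independent seeded streams derived from the `train_config()`
seed, and weight initialization from its own seed, so data order and
initialization can be varied independently.  Identical inputs, seeds and
platform give bitwise-identical histories.

Fine-tuning (`fine_tune()`) is the same protocol started from pretrained
weights, with rigid augmentation applied to every training volume each
time it is drawn: one rotation (uniform within ±5° about a uniformly
chosen grid axis — the rotation parameterization is the package's
choice, the source names only the bound) resampled with a cubic spline,
then an integer translation uniform within ±10 voxels per axis, zero
filled.  Validation volumes are never augmented.  With both bounds zero
the augmentation is exactly the identity and fine-tuning reduces to
training from the pretrained state (asserted in the tests).

## Localization (regression Grad-CAM)

For a subject, let $A^n$ be the $n$-th post-activation feature map of
the last convolutional block (the conventional Grad-CAM capture point;
the source does not disambiguate pre/post activation — post is the
package's recorded choice) and $Z$ the number of units per map.  The
importance weight of map $n$ is the global average of the output
gradient,
$$\alpha_n = \frac{1}{Z}\sum_i\sum_j\sum_k
  \frac{\partial y}{\partial A^n_{ijk}},$$
and the localization map is the weighted combination
$L = \sum_n \alpha_n A^n$.  Because the task is scalar regression, *no*
rectification is applied to $L$: voxels that push the prediction down
are as informative as those that push it up, so negative values are
retained.  Since GAP directly follows the last block, each gradient map
is spatially constant and the closed form
$\partial y / \partial A^n_{ijk} = (\partial y/\partial g_n)/Z$ holds,
with $g$ the pooled feature vector; the head gradient is exact
backpropagation through the dense stages.  The tests verify this against
central finite differences and, for a pass-through head, against the
exact form $L = \frac{1}{Z}\sum_n w_n A^n$.

Per-subject maps are upsampled to the input grid (cubic B-spline,
matching the volume resampler), then standardized to zero mean / unit
variance over the whole grid — upsample-then-standardize is the
package's reading of the published order.  Standardization uses the
whole grid rather than a brain mask (an optional mask is deliberately
not applied by default since the source mentions none).  Because all
volumes share one space, a voxelwise grand average across subjects is
meaningful; it is re-standardized and thresholded at $|Z| > 2$ (the
displayed-stage z-scoring supports re-standardizing the average before
thresholding; this interpretive choice is recorded).  Maps are computed
one subject at a time in evaluation mode, so batch composition cannot
leak into them.

## Volume resampling

`resample_volume()` mirrors the common-space preprocessing step:
separable B-spline interpolation (orders 0–5, default cubic — the
conventional default of the ecosystem the pipeline originates from),
with the recursive prefilter (pole decomposition, mirror boundary) so
the interpolant passes through the original samples.  Output axis
length is `round(n * factor)`, reproducing 182 × 218 × 182 → 91 × 109 ×
91 at factor 0.5; coordinates are endpoint-aligned (output index $i$
maps to input coordinate $i\,(n_{in}-1)/(n_{out}-1)$).  Intensities are
used as stored — no normalization is applied before the network (none
is described for the published pipeline); `standardize_volume()` exists
as an explicit opt-in.

## The phantom generator

`phantom_spec()` defaults define the package's reference study
conditions.  Volumes are 32 × 40 × 32 (2 mm voxels): large enough that
the 8-block architecture with its three pooling stages is exercised
end to end (final feature resolution 4 × 5 × 4), small enough that the
full train-and-explain loop runs on one CPU in minutes — GAP makes the
architecture shape-agnostic, so nothing but the spatial resolution
changes relative to 91 × 109 × 91.  Each volume contains:

* a head-like background ellipsoid (semi-axes 14/18/14 voxels,
  intensity 100);
* two target-coupled spheres, deep (radius 4, β = 1.0 intensity units
  per kg/m²) and lateral (radius 3, β = 0.8), coupling to
  $(t - \bar t)$ so mean intensity is target-independent and a global
  intensity shortcut cannot substitute for localization;
* a separate sex-effect sphere (+2 for males) and a global age effect
  (0.05 per year), giving the covariate fusion something real to absorb;
* white Gaussian noise, sd 2 — per-voxel contrast comparable to the
  1-sd target signal, so single-voxel prediction is hopeless but
  region-averaged prediction is reliable.

Targets are drawn from N(26.15, 4.72²) truncated positive — the female
cohort BMI distribution of the study the architecture comes from — with
age uniform on 45–80 and balanced sex.  All subject-level draws are
seeded per subject, so cohorts are reproducible and a subject's volume
does not depend on cohort size or order.

What the phantom does *not* emulate: anatomy, tissue contrast, bias
fields, registration error, scanner/site effects, or nonlinear
target–intensity relationships.  Passing the phantom acceptance loop
therefore shows that the implementation recovers a known linear signal
and localizes it — not that the published real-data accuracies are
reproduced, which would require the access-restricted cohorts and
GPU-scale training and is explicitly out of scope.

## Problem sizes used by the automated checks

The seeded acceptance runs train the reference architecture at phantom
scale on 240 subjects (160 training, 40 validation, 40 test) for 16
epochs across three seeds — enough for the best-validation-MAE snapshot
to be one where held-out Pearson r clears 0.8 under the default
couplings, while keeping a three-seed run in the minutes range on one
CPU.  The zero-coupling null check reuses the same
pipeline at 6 epochs: with no signal present, the epoch count does not
affect the null distribution of r, only the time spent measuring it.
Protocol-contract tests (determinism, snapshot restore, augmentation
identity) run on 16 × 20 × 16 phantoms, where a full training run takes
seconds.

## Degenerate inputs and edge policies

* `regression_metrics()` on constant predictions reports Pearson r = 0
  with a warning instead of failing (R² and the error metrics remain
  defined).
* `standardize_map()` and `grand_average()` raise a degenerate-map error
  on (near-)zero variance, e.g. when subject maps cancel exactly.
* `localization_score()` returns 0 with a warning when no voxel is
  suprathreshold.
* Ties in the best validation epoch resolve to the earliest epoch.
* `split_cohort()` rounds the validation and test fractions to integers
  and gives any remainder to the training split.
* Cohorts may omit `bmi` for pure prediction; training and evaluation
  refuse such records by name.

## Known limitations

* The engine is single-threaded by design (deterministic, and the
  grading-free way to run on one CPU); wall-clock scales linearly with
  voxels × channels.  Full-scale (91 × 109 × 91) *training* is out of
  desk-scale reach — forward passes and parameter counting at that scale
  are supported and tested.
* Float32 training keeps histories deterministic on a fixed platform but
  not bitwise-identical to float64 runs; snapshot selection can differ
  between precisions on near-tied epochs.
* The B-spline resampler and the rotation augmentation use mirror
  boundary handling for interpolation but zero fill for points mapped
  outside the grid; maps resampled across very few voxels (e.g. 4 × 5 ×
  4 to 91 × 109 × 91) are necessarily smooth and should be read as
  coarse localization, exactly as Grad-CAM maps are.
* Grad-CAM's spatial specificity degrades with the ratio of
  receptive-field size to feature-map spacing.  At the default phantom
  scale the last block has only 4 × 5 × 4 spatial units whose receptive
  fields span most of the volume, and we observe empirically that the
  grand-average map then localizes only diffusely: planted signal
  regions show elevated |Z| relative to the rest of the volume, but the
  extreme |Z| > 2 tail concentrates on structure the model activates
  *consistently across subjects* (e.g. a fixed covariate-effect region)
  rather than on the target-coupled spheres.  Two effects compound
  here.  First, the end-to-end plumbing is spatially exact — with a
  pool-free single-block network, a moved intensity bump moves the map
  peak voxel-for-voxel (this is a unit test) — so the diffusion is a
  property of the deep, thrice-pooled architecture at this grid size,
  not of the implementation.  Second, because the planted signal
  couples to the *deviation* of the target from its mean, its sign
  flips across subjects and its contribution largely cancels in the
  cohort average; what survives averaging is the baseline activation
  pattern of prediction-relevant features.  At biobank scale
  (91 × 109 × 91 input, 12 × 14 × 12 feature grid) the
  field-to-spacing ratio is far more favourable, which is consistent
  with the published grand-average maps isolating specific anatomy.
  Cohort-level thresholded masks from small-volume phantoms should
  therefore be interpreted as "where the model consistently looks",
  and validated quantitatively only at input resolutions that leave
  the last block an adequately fine spatial grid.
* The phantom's linear target coupling cannot probe nonlinear
  brain–trait relationships; a model that only learns linear contrast
  will look perfect here.
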