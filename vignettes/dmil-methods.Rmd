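---
title: "Deep MIL for CT response prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep MIL for CT response prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and
design decisions taken where the published description of this model
family is silent. It states no empirical result that the test suite does
not itself compute.

## 1. The model and its assumptions

The task is weakly supervised: one binary response label per patient, no
slice-level annotation. Multiple-instance learning matches this exactly.
A patient's standardized tumor cuboid (64×64×32 voxels at 1 mm) is a
*bag*; its 32 axial slices are *instances*. The operating MIL assumption
is the standard one: a bag is positive iff at least one instance is
positive, and negative bags contain no positive instance. The pipeline is

1. **Preprocessing.** Trilinear resampling to 1×1×1 mm removes
   scanner-dependent slice thickness (2–5 mm in routine chest CT) and
   pixel size; a fixed 64×64×32 mm crop around the (manually supplied)
   tumor center standardizes the field of view. Slices are windowed,
   scaled to [0, 1], bilinearly resized to the backbone input, replicated
   to three channels and standardized with the natural-image constants.
2. **Shared-weight feature extraction.** Every instance passes through the
   same convolutional backbone (weight sharing is what makes the bag
   representation coherent); global average pooling reduces each
   feature map to an embedding h_k ∈ R^D.
3. **MIL pooling.** Max pooling (order statistics per channel),
   convolutional pooling (a learned K×1 kernel across slices), or
   attention pooling
   z = Σ a_k h_k, a_k = softmax_k(wᵀ tanh(V h_kᵀ)),
   a learned convex combination whose weights expose instance relevance.
   Max and attention pooling are permutation-invariant; convolutional
   pooling is deliberately not (the kernel is indexed by slice position).
4. **Classification.** A single fully connected layer with sigmoid gives
   the response probability; binary cross-entropy is the natural loss for
   a 0–1 bag prediction (the published description names the optimizer and
   rates but not the loss; cross-entropy is the standard pairing).

No deep-learning framework exists in this R stack, so convolution (via
im2col and BLAS matrix products), ReLU, max pooling, global average
pooling, backpropagation and Adam are implemented in base R. The backward
pass is verified against finite differences implicitly through the
training tests (loss decrease, zero-learning-rate invariance,
determinism), and the pooling operators against independent brute-force
oracles.

## 2. Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| target spacing | 1 | mm | published isotropic resolution |
| cuboid shape | 64×64×32 | voxels | published crop containing the whole tumor |
| HU window | [-1000, 400] | HU | unstated in the source; spans air background to soft-tissue/enhancing tumor, the range a lung-mass window covers. Configurable. |
| pad value | -1000 | HU | air; physically neutral outside the thorax |
| channel constants | ImageNet mean/sd | – | the backbones' training distribution; configurable per backbone |
| attention hidden size L | 128 | – | the conventional choice in attention-MIL designs |
| learning rate / batch / epochs | 1e-5 / 32 bags / 50 | – | published training configuration ("10–5" read as 1e-5) |
| checkpoint | best validation AUC | – | unstated; standard practice, falls back to last epoch |
| split ratios | 70:10:20 | – | published; per class, train and validation sizes round half-up, test takes the remainder — this reproduces the published cohort sizes (211/30/60 from 163+138) |

"Batch size 32" is interpreted as 32 *bags* per optimizer step: the bag is
the sample unit in MIL and a bag's instances always travel together. The
alternative reading (32 instances = one bag per step) is available by
setting `batch_bags = 1`.

## 3. Initialization (a deliberate design choice)

Backbone weights are He-normal. The attention parameters start near zero
(sd 1e-3) and the classifier head at exactly zero, so every bag initially
scores 0.5. The reason is quantitative: Adam's step size is ≈ the learning
rate per parameter regardless of gradient magnitude, so a short run at the
published 1e-5 moves each parameter by only ~1e-3. Against a conventional
random head (entries ~1/√D) that movement would be invisible and the
decision direction would simply be the random init. Starting the head at
zero makes the learned direction — tiny as it is — the *only* direction,
which is what lets ranking metrics (AUC) respond to training at small
budgets. Near-zero (not exactly zero) attention init avoids the
two-layer zero-gradient fixed point while keeping initial pooling
effectively uniform.

## 4. The synthetic world

`generate_image_cohort()` emulates the structure of the clinical data, not
its appearance: Gaussian lung-like background (−700 HU, sd 40 HU), one
ellipsoidal tumor (+30 HU, semi-axes drawn from 8–20 mm), and — in
positive bags only — an additive textured signal (mean 200 HU = 5 noise
sd, pixelwise uniform texture) on a randomly chosen subset of the cuboid's
axial slices. The signal is injected per slice so attention weights have a
slice-level ground truth; the whole chosen slice carries it, making the
slice (not a sub-region) the positive instance. Default volumes are
generated at 1 mm isotropic spacing so that slice-level ground truth
survives resampling exactly; anisotropic resampling is exercised
separately by the preprocessing tests. `generate_embedding_cohort()` is
the fast counterpart: standard-normal instances, with signal instances
shifted along a fixed random direction by `signal_effect / noise_sd` sd.

What this world does **not** emulate: lung anatomy, reconstruction
physics, intra-tumor heterogeneity, or a response signal confined to
tumor tissue. In particular, the slice-wide signal is an idealization —
it makes positive bags separable by intensity statistics that a *randomly
initialized* tiny backbone can expose, which is exactly what the
end-to-end tests need to validate plumbing at desk scale. A green
end-to-end test therefore establishes that the pipeline trains, splits,
scores and evaluates correctly under the MIL assumption; it does not
establish clinical-grade performance, which in the original study depends
on pretrained features and real cohorts. (A harder variant developed
during design — signal confined to the tumor cross-section — introduces a
tumor-size confound that a near-frozen random backbone cannot cancel;
that variant is documented in the package history rather than used as the
default world.)

## 5. Numerical choices

- **Softmax** is computed with max-subtraction; attention weights sum to 1
  within 1e-6 even for score magnitudes of 1e4 (tested).
- **Interpolation** is trilinear (volumes) and bilinear (slices), with the
  half-pixel-center convention for resizing and border clamping for
  samples beyond the grid; both are checked against brute-force
  physical-coordinate oracles at 1e-5.
- **Crop centering** for even extents puts the center voxel at 0-based
  index extent/2 per axis (1-based (33, 33, 17)); the low side gets the
  extra voxel.
- **Positivity** is `score >= cutoff` (closed on the left); response
  (label 1) is the positive class. Both conventions are configurable
  because the published sensitivity/specificity pair is not arithmetically
  consistent with the published confusion counts — only accuracy is, so
  only accuracy is used as a reproduction target.
- **Cut-off ties** break toward the lower threshold.
- **AUC** is the rank-based Mann–Whitney statistic with half-credit for
  ties (equals the trapezoid of the tie-grouped ROC); the CI is DeLong by
  default (deterministic), stratified percentile bootstrap as an option.
- **Degenerate denominators** (empty prediction classes) yield 0 with a
  warning rather than NaN.
- **BCE** is computed from logits in the numerically stable softplus form.

## 6. Design choices where the design was open

- JSON (not YAML) run configs: no YAML parser is available in the target
  stack, and `jsonlite` is; the schema is validated with unknown keys
  rejected before any work.
- NIfTI-1 I/O is a minimal purpose-built reader/writer (float32 written;
  uint8/int16/int32/float32/float64 and both endiannesses read, with
  scl slope/intercept). DICOM series reading is out of scope offline.
- The backbone registry constructs `vgg16`, `alexnet` and `tiny_test`
  from their published layer configurations with random weights;
  `resnet34`, `densenet` and `mobilenet_v2` are registered with their
  metadata but refuse to build, because their residual/dense blocks would
  have to be re-derived rather than consumed and no pretrained source
  exists offline. `pretrained = TRUE` errors loudly instead of silently
  using random weights.
- Convolutional pooling carries no bias (the minimal K×1 convolution);
  its kernel initializes to uniform 1/K (plain averaging).
- Gated or multi-head attention is deliberately not implemented; the
  tanh-only two-layer scorer is the published form.

## 7. Known limitations

- Training at the published 1e-5 for tens of steps changes parameters by
  ~1e-3; with the CPU-scale backbone this suffices for ranking (AUC) but
  produces probabilities that remain near 0.5 — calibrated probabilities
  require longer schedules or larger rates.
- The hand-rolled conv core is single-threaded BLAS-bound; a VGG16
  forward pass over a full 32-instance bag costs minutes rather than
  seconds on one CPU — fine for tests, not for cohort-scale VGG16
  training, which is what the pluggable backbone contract (and the
  embedding route) is for.
- No augmentation, weight decay, early stopping or class weighting: the
  source description does not state them, so they are absent by default
  rather than silently added.
- `simulate()` on a fitted model draws labels at fitted probabilities;
  it is a generative view of the fitted cohort, not a CT simulator.
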