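---
title: "Pathological gait recognition from fused energy images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathological gait recognition from fused energy images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neurological disorders leave signatures in the way people walk: Parkinsonian
patients show festinating (hurried, forward-leaning, small-stepped) and
shuffling gait, spastic paraplegia produces a scissoring leg pattern, and
hemiparesis a circumducted swing of one leg. `pathogait` implements a
side-view, silhouette-based recognition pipeline for five gait classes
(festinating, scissor, hemiparetic, shuffling, normal): silhouette cleanup,
automatic gait-cycle segmentation, construction of a fused energy image
(FEI) per cycle, and a lightweight dual-branch convolutional classifier with
a parallel attention block. Because clinical gait video is hard to share, the
package also contains a parametric silhouette-walker generator that renders
class-separable synthetic sequences with known ground truth, making every
stage testable end to end.

## Gait-cycle segmentation

A walker's height is nearly constant while the silhouette's width swings
with the legs, so the width-to-height ratio of the tight axis-aligned
bounding box of the body contour oscillates with two troughs (legs-together
poses) per gait cycle; three consecutive troughs delimit one full cycle.
The contour is taken as the Sobel gradient magnitude of the binary
silhouette, masked to the foreground so a filled region yields its one-pixel
inner boundary.

Numerical choices, made here because no standard values exist:

* **Smoothing window 3 frames** (centered moving average). The fastest
  cadence we model (festinating, ~14 frames per cycle) has a ratio period of
  ~7 frames; a 5-frame window attenuates that oscillation enough to push it
  under the prominence threshold, a 3-frame window does not.
* **Trough prominence 0.01, minimum separation 5 frames.** Prominence is
  topographic (climb to the lowest enclosing saddle). Candidate minima are
  plateau-aware — pixel quantization flattens the legs-together pose into a
  short plateau, and the plateau center is reported.
* **Boundary troughs.** A recording usually starts or ends near a
  legs-together pose. The first/last sample counts as a trough when the
  series rises away from it with sufficient prominence; without this, the
  closing trough of the final cycle (which falls on the last frame) would be
  lost and a three-cycle recording would segment into two.
* Frames with empty foreground get their ratio linearly interpolated from
  neighbours.

## Energy templates and fusion

For a cycle of \(N\) binary frames \(F_t(x,y)\in\{0,255\}\):

* **GEI** \(= \frac1N\sum_t F_t\) — static + dynamic shape.
* **GEnI**: per pixel, the Shannon entropy of foreground occupancy
  (\(K=2\) states), min–max scaled to \([0,255]\); static pixels go to 0,
  half-occupied pixels to 255. A cycle whose entropy field is constant
  yields an all-zero image with a warning.
* **AEI** \(= \frac1{N-1}\sum_{t=2}^{N} |F_t - F_{t-1}|\) — pure motion.
  The \(1/(N-1)\) normalization (rather than \(1/N\) with an undefined
  zeroth frame) is chosen so a fully alternating pixel saturates at 255.

The FEI is the convex combination \(w_1\,\mathrm{GEI} + w_2\,\mathrm{GEnI}
+ w_3\,\mathrm{AEI}\) whose weights minimize the squared reconstruction
error against a target image, by full-batch gradient descent with the
weights kept on the probability simplex (negative components clipped, then
renormalized to sum 1). Design notes:

* **The target image is a free choice** — nothing in the formulation pins it
  down, so it is a caller-supplied parameter. The pipeline default is the
  per-pixel **maximum** of the three templates: it emphasizes every
  template's high-energy regions and keeps all three weights active. A
  `"mean"` target and arbitrary target images are supported.
* **Exact quadratic structure.** The cost is quadratic in the three weights,
  so the \(3\times3\) Gram matrix is computed once and each iteration costs
  O(1) regardless of image size; the descent is algebraically identical to
  operating on the full pixel matrix.
* **Step size** defaults to \(0.9\,n_\text{pixels}/\lambda_{\max}(2G)\),
  the largest stable fixed step for the quadratic; templates are internally
  rescaled to \([0,1]\). With correlated (ill-conditioned) templates a
  small fixed step would need far more than 10^4 iterations to recover
  planted weights to \(10^{-3}\), hence the spectral default. `max_iter`
  defaults to 20000 (iterations are O(1)) and the stop rule is a cost change
  below `1e-8`.
* **Restarts.** Five descents — one from the uniform initialization
  \(w_i = 1/3\), four from seeded random simplex points — guard against the
  clipping step parking a run on a simplex face; the lowest-cost run wins.
  Weights are fitted per cycle (each cycle gets its own weights).

## The classifier

A width-1.0 MobileNetV2-style feature extractor (inverted residual
bottlenecks, linear projections, ReLU6, final 1×1 expansion to 1280
channels, stride 32) feeds two branches: the raw convolutional features, and
the same features re-weighted by the attention block. The branches are fused
**elementwise (sum)** and classified by a depthwise-separable head:
depthwise 3×3, pointwise to 32 channels, flatten, dense 256, batch-norm,
rectifier, dropout 0.2, dense to 5 classes, softmax.

* **Shared backbone, sum fusion, head widths 32/256.** The architecture's
  published size (~3.01 M trainable parameters at 256×256 input, ~2.89 M at
  224×224, the two differing only in the flatten→dense weights) is only
  attainable with one shared backbone and channel-preserving fusion; two
  independent backbones would add another 2.2 M parameters. The head widths
  are calibrated to that same budget. `fusion = "concat"` is available
  behind a flag.
* **Attention block** (1280 channels, reduction 16): channel attention is a
  shared two-layer MLP (1280→80→1280, rectifier hidden, biases on both
  layers) applied to the global average- and max-pooled descriptors, summed,
  sigmoid. Spatial attention stacks the per-pixel mean and max over channels
  into a 2-channel map, applies a depthwise 7×7 convolution (padding 3) and
  a pointwise 1×1 to one channel, sigmoid. Both maps are computed from the
  *original* input and multiplied in (parallel topology) — a serial
  reference (`apply_cbam_serial()`) demonstrably differs. Reduction 16 is
  the standard default and the only value consistent with the block adding
  ~0.21 M parameters over a 1-D-conv (ECA-style) channel attention at 1280
  channels.
* **Single-channel stem.** Grayscale FEIs enter a 1-channel stem; when
  externally trained RGB weights are loaded the input is replicated to three
  channels instead.

## Training and initialization

There is no deep-learning framework in this package's dependency set: the
forward pass, parameter counting, and backpropagation are implemented
directly (R with C++ convolution kernels). Training follows the
transfer-learning regime: the backbone is **frozen**, its features are
computed once per sample and cached, and only the attention block and head
are optimized (Adam, cross-entropy, batch 32). Gradients are validated
against central finite differences in the test suite. Consequences:

* End-to-end fine-tuning of the backbone is out of scope.
* Without bundled pretrained weights the frozen backbone is a *random*
  feature extractor. Initialization matters: convolutions feeding ReLU6 use
  He-normal initialization, while the linear bottleneck projections use
  gain-1 (Xavier-style) scaling so activation variance neither explodes
  (saturating every ReLU6) nor dies across the 50+ layer stack. Random
  deep features preserve class geometry well enough for the head to
  separate the synthetic classes.
* Head batch-norm uses batch statistics during training (running statistics,
  momentum 0.1, at evaluation); dropout is seeded.

Defaults follow the standard recipe for this model family (learning rate
1e-4, batch 32, 100 epochs, 80/20 stratified split). The synthetic
end-to-end benchmark in the tests uses a shortened schedule — 15 epochs at
learning rate 1e-3 — because 15 epochs on 160 samples is only ~75 Adam
steps, too few for the 1e-4 step size to move a freshly initialized head;
the higher rate is the natural choice for that schedule, not a tuned value.

The split is stratified by class. Note the sample unit is a gait *cycle*,
so cycles of the same walking pass can land on both sides of the split; an
evaluation stricter about subject leakage would split by sequence.

## The synthetic walker

Closed-form geometry, no physics: a torso ellipse (tiltable for trunk
lean), a head disc, and two legs drawn as thick hip→knee→foot segments.
Foot separation follows \(\sin(2\pi t/T)\), so legs-together poses — the
aspect-ratio troughs — fall exactly on multiples of \(T/2\), which the
generator emits as ground truth (the closing trough of the last cycle is
clamped to the final frame). Class styles are deliberate caricatures of the
clinical descriptions, chosen once for separability rather than
biomechanical realism:

| class       | cycle (frames) | stride (px) | lean (deg) | step height | special |
|-------------|---------------|-------------|-----------|-------------|---------|
| normal      | 24 | 60 | 0  | 14 | — |
| festinating | 14 | 36 | 18 | 8  | fast, leaning |
| scissor     | 26 | 38 | 4  | 10 | knees cross midline during swing |
| hemiparetic | 26 | 48 | 0  | 12 | one leg wider + circumduction arc |
| shuffling   | 28 | 30 | 6  | 2  | feet barely leave ground |

Scissor crossing is implemented as a phase-proportional knee displacement
across the midline (not a static offset), so the legs-together pose remains
the width minimum and ground-truth troughs coincide with aspect-ratio
troughs. Dataset generation jitters stride (±8%), cadence (±2 frames), lean
(±1 degree), and step height (±10%) per sample. Pixel noise (`noise_rate`)
flips up to 5% of pixels; the morphological cleanup in preprocessing absorbs
it.

**What passing tests show — and don't.** The generator produces clean,
single-component, constant-height silhouettes with strictly periodic
motion. Success on it validates the machinery (segmentation recovers known
cycles; templates match their definitions; fusion recovers planted weights;
the classifier separates classes that are separable by construction). It
does not certify performance on real clinical video, where segmentation
artifacts, clothing, occlusion, view changes, and within-class variability
dominate.

## Problem sizes

The test suite's end-to-end benchmark uses 20 sequences per class of 2
cycles each (40 cycles/class, 200 FEIs), a 160/40 stratified split, and 15
training epochs — small enough to run routinely on one CPU while leaving
every class with a meaningful test count. The remaining tests use toy
fixtures (16×16 cycles, 4–8 channel feature maps) against brute-force
oracles.

## Known limitations

* The fusion target is a documented guess (`"max"` by default); different
  targets yield different weights and there is no external ground truth for
  which is "right".
* The backbone cannot be fine-tuned end to end, and no pretrained weights
  ship with the package (offline build); `apply_transfer_learning()` can
  load a compatible externally serialized backbone.
* The walker is 2-D, single-view, and noise is i.i.d. salt-and-pepper —
  none of the structured artifacts of real background subtraction.
* Forward passes run at CPU speed (~1 s per 256×256 image); this is a
  research implementation, not a deployment path.
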