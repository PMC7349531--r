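---
title: "Segmenting retinal pigment signs with a dense encoder-decoder network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting retinal pigment signs with a dense encoder-decoder network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsnet)
```

## The problem

Retinitis pigmentosa (RP) deposits small dark pigment signs on the retinal
surface that are visible in color fundus photographs. Counting, sizing and
locating these deposits over successive visits is how clinicians track
disease progression, but the deposits are tiny — typically well under 1% of
the image's pixels — and fundus image quality is poor, so segmenting them
is a severely class-imbalanced, low-signal problem. `rpsnet` implements a
complete desk-scale pipeline for this task: a densely connected
encoder-decoder segmentation network, the augmentation and class-balancing
recipe needed to train it on a small patient cohort, patient-wise
cross-validation, pixel-level evaluation, and connected-component analytics
of the segmented deposits.

## The network

The model is a fully convolutional encoder-decoder. The encoder has four
dense blocks; block $i$ applies

* a 3x3 convolution with batch-norm and ReLU, producing $T(F_i)$,
* a plain (linear) 3x3 convolution on that, producing $\tilde T(F_i)$,
* a depth-wise concatenation $P_i = T(F_i) * \tilde T(F_i)$,
* a 1x1 "bottleneck" convolution with batch-norm and ReLU that limits the
  doubled channel count back to the block width ($\Delta P_i$),
* 2x2/stride-2 max pooling that records, for every window, the argmax
  position and the pre-pool spatial size.

Block widths are 64/128/256/512. The decoder mirrors the encoder: each of
its four blocks starts with max-unpooling, which places every value back at
the recorded argmax position of the paired encoder pooling stage (zeros
elsewhere) and restores the exact pre-pool size — so a 300x400 input comes
back at 300x400 without any cropping. After two convolutions the decoder
concatenates three features, $Q_i = T(G_j) * \tilde T(G_i) * T(F_i)$: its
own two convolution outputs plus the paired encoder block's
first-convolution feature imported over an external dense path. These
dense paths inside and between encoder and decoder are the architecture's
central idea: high-frequency detail lost to convolution and pooling is
re-injected where it matters, which is what lets the network segment
deposits of a few dozen pixels. The final bottleneck narrows to 2 channels
and a per-pixel softmax produces class probabilities.

The full-size network has exactly sixteen 3x3 convolutions and eight 1x1
bottlenecks and totals 10,504,396 trainable parameters (10.5 M), counting
each convolution's kernel and bias and each batch-norm's scale and shift —
`count_trainable_parameters(rps_spec())` recomputes this and the test suite
checks it against independent per-layer arithmetic. `layer_shape_table()`
reproduces the full feature-map geometry, including the 18x25 deepest
encoder map for a 300x400 input and the 1280-channel deepest decoder
concatenation.

### Reading of the published layer table

Two details of the published layout require interpretation, resolved here
as follows:

* The second convolution of deeper encoder blocks is listed with a
  64-deep kernel, which is inconsistent with its input; each second
  convolution's kernel depth is taken to equal the first convolution's
  output width (128/256/512). Only this reading reproduces both the
  concatenation channel counts and the 10.5 M parameter total.
* Layers not flagged with batch-norm (each block's second convolution)
  are plain linear convolutions: no normalization, no activation.

Other fixed conventions: bottleneck order is 1x1 convolution, then
batch-norm, then ReLU (including the final 2-channel bottleneck before the
softmax); concatenation order follows the block equations with the
imported encoder feature last; pooling uses 2x2 windows with stride 2,
floor on odd sizes, ties resolved to the first window position in
row-major order; 3x3 convolutions use symmetric 1-pixel zero padding; all
convolutions carry biases. Weight initialization (unspecified in the
original description) is He-normal for convolution kernels with zero
biases and batch-norm scale 1 / shift 0, under a caller-supplied seed.

### Numerical engine

No deep-learning framework is assumed: convolution forward and backward
passes are implemented as im2col + GEMM in C++ (RcppArmadillo), with
max-pooling/unpooling as scatter/gather on the recorded indices and
batch-norm, activations and the optimizer in R. The full backward pass is
verified against central finite differences in the test suite. Batch
normalization uses minibatch statistics both in training and prediction
(instance statistics at batch size 1): desk-scale runs are too short for
meaningful running averages, and using batch statistics keeps evaluation
consistent with training on the same pairs.

## Training recipe

Class imbalance is countered by median-frequency balancing: with
$\mathrm{freq}(c)$ = pixels of class $c$ divided by the total pixels of
the images in which class $c$ appears, the loss weight of class $c$ is
$\mathrm{median}(\mathrm{freq})/\mathrm{freq}(c)$ (for two classes the
median is their midpoint, so $w_c \cdot \mathrm{freq}(c)$ is constant).
The loss is the weighted per-pixel cross-entropy, mean over pixels of
$w_{y}\,(-\log p_{y})$ with probabilities floored at $10^{-12}$. Weights
are computed on the training fold only, before augmentation.

The full-scale configuration (`rps_train_config()` defaults) is Adam with
constant learning rate $10^{-4}$ and epsilon $10^{-6}$, minibatches of 10,
20 epochs, reshuffling every epoch. Optional global-L2 gradient clipping is
available but off by default, since no threshold is published. Training is
deterministic given the seed.

Data flows through patient-wise 4-fold cross-validation: each fold holds
out every image of one patient, so test patients are never seen in
training, and augmentation is applied only to the training side. The
four-stage cascade adds, in order: horizontal and vertical flips of every
input (x3); a (+5, -5)-pixel translation of everything so far (x2); a
(-5, +5) translation composed with a horizontal flip (x2); and a
(+10, +10) translation composed with a vertical flip (x2) — a x24
expansion, 90 training images becoming 270, 540, 1080 and 2160. Flips and
translations act identically on image and mask; translation vacates
borders to black, the natural fill for fundus images. Positive x shifts
toward higher column index and positive y toward higher row index; the
axis convention is internal, since the cascade's content is symmetric in
sign.

## Evaluation

Predictions are scored pixel-wise: TP/FN/FP/TN tallies feed sensitivity,
specificity, precision, accuracy and F-score. Degenerate 0/0 ratios (a
healthy image with an empty prediction) report 0 and are flagged rather
than silently dropped. Fold-level results pool the pixel counts across
images (micro-averaging) — per-image averaging is also reported per row of
the returned table. When native-resolution ground truth is supplied, the
pigment-probability map is first upscaled by bilinear interpolation and
thresholded afterwards (interpolating the probability rather than the
binary mask keeps labels binary by construction); the binarization
threshold is 0.5, equivalent to per-pixel argmax for two classes. ROC
curves sweep the threshold over the pooled pigment probabilities,
computing AUC by the trapezoidal rule and the equal-error-rate point
(sensitivity = specificity) by linear interpolation; by default the ROC is
computed at training resolution, with a flag for native resolution.

## Pigment analytics

Segmented masks are quantified by connected-component labeling under
8-connectivity — deposits are irregular, and 4-connectivity would split
diagonal strands. Each region reports its pixel area, its centroid
(0-based coordinates, x = column) and bounding box; regions are ordered by
area, ties by top-left corner. Reports add pairwise Euclidean centroid
distances, and `compare_visits()` matches regions between two visits by
greedy nearest-centroid pairing within a configurable radius (default
30 px), reporting per-pair area change and displacement plus
appeared/disappeared regions. Greedy matching equals optimal assignment
whenever displacements are small against inter-deposit spacing, the
clinically relevant regime; the suite checks this against an exhaustive
assignment oracle on small instances.

## The synthetic cohort

Real RP fundus data with expert masks is external and cannot ship with the
package, so a generator emulates the structure the pipeline needs: a
bright circular retina field on dark corners with low-frequency texture, a
brighter optic-disc disc, darker curved vessel strokes radiating from it,
and dark irregular pigment deposits grown by randomized accretion from
seed pixels — whose exact pixels define the mask. Deposits are placed
non-overlapping with a 2-pixel exclusion halo inside the retina field.
Per-image pigment is capped at 4% of pixels (drawn areas are scaled down
if needed), preserving the severe imbalance of real data at any image
size. The default cohort mirrors the reference layout: 4 patients x 30
images (5 images x 2 eyes x 3 sessions), 21 of 120 images healthy, with
per-patient tint and vessel-density shifts so cross-validation folds are
distribution-shifted like real patients. Generation is fully deterministic
given the cohort seed.

What the generator does **not** emulate: real optic-disc morphology,
vessel branching, illumination artifacts, inter-grader disagreement, or
pigment texture. Passing tests therefore demonstrate that the
architecture, optimization and evaluation machinery are correct and that
the network has the capacity to fit fundus-like image/mask pairs — not
that this implementation reaches any particular accuracy on real RP data,
which would require the external cohort and full-scale training.

## Desk-scale experiment sizes

All shipped experiments are sized for a single CPU. The capacity check
trains a reduced-width network (block widths 8/16/32/64) on two synthetic
64x64 pairs for 300 single-image Adam iterations at learning rate 0.05 and
requires a training-set F-score of at least 0.9; it completes in about two
minutes. The higher learning rate (vs. the full-scale 1e-4) matches the
tiny problem: at low rates the optimizer lingers in a regime where the
dark out-of-field corners are labeled pigment, and 300 iterations are not
enough to leave it. The augmentation cascade is exercised on 64x64 images
(90 to 2160 pairs); architecture checks (parameter totals, geometry) run
at full size, since they cost only arithmetic.

## Known limitations

* Training at the full 300x400 resolution with 64-512 filters is
  supported but slow on CPU; the package is a faithful desk-scale
  implementation, not a GPU harness.
* Only binary (background/pigment) segmentation is exercised, although
  `n_classes` generalizes trivially.
* Visit matching tracks two visits at a time and does not calibrate pixel
  distances to physical units.
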