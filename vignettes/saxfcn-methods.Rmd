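---
title: "Methods: FCN segmentation of the left ventricle in short-axis MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FCN segmentation of the left ventricle in short-axis MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(saxfcn)
```

This vignette is the package's own account of the model, its assumptions,
the numerical choices that were genuinely open, and what the synthetic-data
tests do and do not establish. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The task and the data model

Short-axis cardiac MR slices are segmented per pixel into background (0),
LV cavity (1) and myocardium (2). Delayed-enhancement label volumes use
five codes (0–4, with infarction = 3 and no-reflow = 4 subdividing the
wall); since the segmentation target here is the wall as a whole, the
default remapping `{0→0, 1→1, 2→2, 3→2, 4→2}` folds the pathology codes
into myocardium. This is the only remap consistent with a three-class
background/cavity/wall task; it is configurable in `remap_labels()`.

Conversion from 3D NIfTI to 2D slices applies min–max normalization per
slice, `round_half_up(255 · (x − min)/(max − min))`, then resizes to
256 × 192. Open choices, resolved as follows:

* **Normalization scope** — per-slice, not per-volume: after conversion the
  pipeline only ever sees 2D images, so per-slice bounds are the only
  information available downstream. (Whether the original work normalized
  per slice or per volume is not stated.)
* **Rounding** — half-up, so label 1 of a {0, 1, 2} matrix maps to
  127.5 → 128, reproducing the printed {0, 128, 255} levels. R's default
  banker's rounding would give 128 here too, but half-up is fixed
  explicitly so the contract is unambiguous at every .5 boundary.
* **Constant slices** — a degenerate (all-equal) matrix has no dynamic
  range and maps to zeros with a warning rather than an error: empty
  (all-background) label slices are a normal occurrence in basal/apical
  positions.
* **Interpolation** — bilinear for images, nearest-neighbour for masks.
  Nothing else is defensible for labels: any averaging interpolation can
  fabricate classes that exist in neither source pixel.
* **Resize vs crop** — resize was chosen (crop/pad would discard anatomy
  when the field of view is smaller than 256 × 192); the target size is a
  parameter, so a crop-based front end could be added without touching the
  rest.
* **Slice axis** — the third array axis, matching slice-last short-axis
  stacks; the NIfTI affine is not interpreted.

## Class weighting

Background exceeds 85 % of pixels, so the loss uses inverse-frequency class
weights. The bare prescription "weights are the inverse of the class
frequencies" leaves a normalization constant free; we fix `w_c = 1/(C·f_c)`
so that uniform frequencies give unit weights and, for every present
class, `w_c · f_c = 1/C` exactly — each class contributes equally to the
expected loss, and the loss scale is comparable across class counts and
learning rates. Two further choices:

* weights are computed on the **training split only** (no leakage);
* an absent class (`f_c = 0`) gets weight 0 plus a warning, not ∞ or an
  error, so an all-background batch cannot crash training.

## The network

The 15-layer encoder–decoder is fixed by contract: 3 × 3 same-padded
convolutions with widths 16/32/64, batch normalization and ReLU after each,
one 2 × 2/stride-2 max-pool, a 4 × 4/stride-2 transpose convolution back to
full resolution with 16 channels, a final 3 × 3 convolution onto C class
channels, softmax, pixel classification. `fcn_spec()` rejects any other
kernel geometry. Points the published layer table leaves ambiguous:

* **Transpose-conv output size.** The table prints 128 × 96 × 16 for the
  transpose convolution yet 256 × 192 for the following convolution; a
  stride-2 4 × 4 transpose convolution from 128 × 96 yields 258 × 194 raw,
  and the only shape-consistent reading is a symmetric one-pixel crop to
  256 × 192. That is what `.tconv_fw` implements, bit-exactly: raw output
  `2H + 2`, crop rows/columns `2..(2H+1)`.
* **Final-layer learnables** are printed with batch-norm vocabulary
  ("Offset/Scale"); they are implemented as ordinary weights + bias, which
  is the only reading that makes the printed shapes
  (3 × 3 × 16 × 2 and 1 × 1 × 2) meaningful. The total learnable count for
  C = 2, summing every printed tensor, is 40 210, asserted in the tests.
* **Class count.** The table prints C = 2 softmax channels while the
  weighting and confusion matrices use three classes; `num_classes`
  defaults to 3 with C = 2 supported, and the architecture checks are run
  at C = 2 to mirror the table literally.
* **Unstated initialization details**, fixed by config: He-uniform weight
  init from a seed, zero biases; batch-norm ε = 1e−5, running statistics
  updated with rate 0.1 (batch statistics in training, running statistics
  in inference); input images scaled to [0, 1] before the first
  convolution.

Because no deep-learning framework is available in this stack, the layers
and their backward passes are implemented here (Rcpp/RcppArmadillo,
im2col + GEMM). Correctness is anchored two ways: forward kernels against
naive loop oracles, and the entire backward pass against central finite
differences of the loss with respect to every parameter tensor (relative
error < 1e−4 asserted; observed ~1e−9).

## Training

Weighted cross-entropy, normalized by the **sum of applied weights** rather
than the pixel count — this makes the loss invariant to a common rescaling
of the weights and keeps its magnitude stable across imbalance levels (the
normalization is otherwise unstated). Probabilities are clipped at 1e−12
inside the log. Solvers use their canonical defaults, fixed in
`train_config()`: SGDM momentum 0.9; Adam β = (0.9, 0.999), ε = 1e−8 with
bias correction; RMSProp decay 0.99, ε = 1e−8. Per-epoch shuffling is
seeded; there is no early stopping, no LR schedule and no augmentation —
runs are fixed-epoch, matching the experimental design being mirrored
(epoch budgets 30/50/100/150, learning rates 0.01/0.001, mini-batches
4/8, compared across the three solvers by `hyperparameter_sweep()`).
"Mini-batch accuracy" is pixel accuracy of the forward pass on the current
batch, recorded every iteration.

## Metrics

All ratio metrics derive from one-vs-rest reductions of a pixel confusion
matrix accumulated over the evaluated slices (micro aggregation; a
per-slice macro mode would average ratios of very different denominators
and is deliberately not the default). Undefined 0/0 ratios score 1 when
the class is absent from both masks (nothing to get wrong) and 0 when it
is absent from exactly one (pure miss or pure false alarm). Aggregates are
unweighted means over the foreground classes, with per-class values always
reported alongside. The boundary-F1 score uses boundary pixels defined as
class pixels with a 4-neighbour outside the region (image border counts as
outside), a match tolerance defaulting to 0.75 % of the image diagonal
rounded up, and averages per-slice class means over slices. The exact
identity `dice = 2·jaccard/(1 + jaccard)` and equivalence with an
independent brute-force implementation on random mask pairs are asserted
in the tests.

## The phantom generator

`generate_phantom()` emulates exactly the statistics the pipeline depends
on: a roughly circular bright cavity (radius 12–26 px at 256 × 192) inside
an annular wall (6–14 px thick), centre jitter, per-tissue Gaussian
intensities (means 30/200/110, SDs 15/20/18 on the 8-bit scale) whose
distributions overlap enough to defeat global thresholding, a smooth
multiplicative bias field (amplitude 0.05), and an `apical_shrink` factor
(default 0.05 per slice index) mimicking the taper towards the apex.
Background occupies > 85 % of pixels at default size, reproducing the
imbalance that motivates the weighting. Slice k of a dataset uses seed
`seed + k`; everything is a pure function of (parameters, seed).

It does **not** model MR physics (k-space, coil profiles, partial-volume
effects), pathology textures, inter-subject shape variability, papillary
muscles, or neighbouring structures. Consequently a green end-to-end test
establishes that the implementation — conversion, weighting, gradients,
solvers, metrics — is correct and that the architecture can learn
shape-from-context on imbalanced data; it does not establish clinical
segmentation accuracy, and the headline clinical-dataset numbers are out
of reach by design (no clinical data ships with, or is downloaded by, this
package).

## Scaled-down acceptance surrogates

The two training-based acceptance tests run on 64 × 48 phantoms rather
than 256 × 192 to fit a single-CPU time budget. The network is fully
convolutional, so its architecture and parameter count are unchanged
(asserted); slice count (80 training slices), solver (Adam), learning rate
(0.001), mini-batch (4) and the ≤ 50-epoch cap are kept as stated, with 8
epochs used in practice. Thresholds (held-out foreground Dice ≥ 0.85,
≥ 0.3 above the all-background baseline; Adam ≥ SGDM in ≥ 2 of 3 seeds)
were fixed before measurement and are asserted unchanged. The "stochastic
over 3 seeds" aggregation for the Dice criterion is interpreted as "≥ 2 of
3 seeds pass", mirroring the rule the solver-ordering criterion states
explicitly; the median Dice over the three seeds is additionally required
to clear the threshold.

## Known limitations

* Single encoder/decoder level: the receptive field is small, adequate for
  phantom geometry and the published design, but not a general-purpose
  segmentation architecture (deliberately: no skip connections, no deeper
  variants).
* The NIfTI reader handles the common single-file subset (datatypes
  uint8/int8/int16/uint16/int32/float32/float64, slope/intercept scaling)
  and ignores orientation metadata; exotic or 4D+ studies should be
  converted externally.
* Training is single-threaded CPU R/C++; at full 256 × 192 resolution it
  is usable for tens of epochs on small datasets, not for large-scale
  experiments.
* BF-score distances are exact all-pairs computations, fine for slice-size
  boundaries but quadratic in boundary length.
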