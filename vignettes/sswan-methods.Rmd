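---
title: "SSW-AN: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSW-AN: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic phantoms do and do not emulate, the numerical choices, and the
design decisions taken where the architecture description left things
open.

## The model

SSW-AN is a residual-learning network that operates on the single-level
2D discrete wavelet transform of a bicubic baseline image rather than on
pixels.  For an input slice $F \in \mathbb{R}^{r \times c}$ (z-scored
per image):

1. A bicubic baseline $F_{bic}$ is formed by downsampling $F$ by a
   factor $s$ (default 2) and bicubically upsampling back.  $F_{bic}$
   carries the low-frequency content; everything the network must add is
   the residual $F - F_{bic}$.
2. The orthonormal DWT splits $F_{bic}$ into four channels
   $(LL, LH, HL, HH)$ at resolution $(r/2, c/2)$.  Because the transform
   is orthogonal, it is exactly invertible and energy-preserving, so the
   representation loses nothing and keeps per-band structure separate.
3. A 5x5 convolution with leaky-ReLU produces $w$ shallow feature
   channels $I_0$.  The activation must be leaky: wavelet detail
   coefficients are signed, and a hard ReLU would discard half of them.
4. $T$ identical attention blocks refine the features.  One block is
   $$I_{f+1} = \mathrm{spa}(\mathrm{chn}(W_{3\times3} I_f)) + I_f .$$
   Channel attention pools each channel globally by max and by average,
   passes both vectors through one *shared* two-layer MLP with hidden
   width $w/h$, sums, and applies a sigmoid; the resulting per-channel
   gate multiplies the features.  Spatial attention pools across
   channels (max and average), convolves the two stacked maps with a
   7x7 kernel, applies a sigmoid, and multiplies every channel by the
   resulting per-position gate.  The local skip keeps each block
   near-identity at initialization.
5. The $T$ block outputs are concatenated channel-wise (width $wT$) so
   that every block receives direct gradient from the loss, then fused:
   a 3x3 convolution to width $w$, leaky-ReLU, and a 3x3 convolution to
   4 channels gives the predicted residual coefficients $I_c$.
6. Reconstruction is $\hat F = \mathrm{IDWT}(I_c) + F_{bic}$ (global
   residual learning); with all fusion weights zero the model returns
   the baseline unchanged, which is the correct neutral behaviour.

The architecture as published is purely reconstructive; it never states
how class scores are produced.  The segmentation head here is therefore
deliberately minimal and isolated in one operation: a 1x1 convolution
from the fused width-$w$ features to $L$ channels at coefficient
resolution, bilinear upsampling to input resolution, and a softmax.
Anything smarter (decoder, skip connections from the image domain)
would change the method being studied.

## Losses

Training minimizes
$$\mathcal{L} = \lambda_{dice} \, K_{dice} + \lambda_{rec} \,
\mathrm{MSE}(\hat F, F) + \lambda \sum_W \|W\|_2^2 ,$$
defaults $\lambda_{dice} = \lambda_{rec} = 1$, $\lambda = 10^{-4}$ (L2
on weights only, not biases).  $K_{dice}$ is the squared-sum soft Dice
loss with uniform class weights $\omega_l = 1/L$:
$$K_{dice} = 1 - \sum_l \omega_l
\frac{2 \sum_g p_{l,g} t_{l,g} + \varepsilon}
     {\sum_g p_{l,g}^2 + \sum_g t_{l,g}^2 + \varepsilon}.$$
Whether the reconstruction objective should be a separate pretext phase
or trained jointly is not specified by the architecture description;
the package trains jointly with configurable weights, which also
guarantees that every parameter group (including the final
coefficient-producing convolution, which the Dice term cannot reach)
receives gradient.

Numerical choices:

* $\varepsilon = 10^{-6}$ appears in the numerator *and* denominator.
  With a denominator-only smoothing, a perfect prediction would score a
  small positive loss and an empty class would contribute a spurious
  penalty; with both, perfect overlap gives exactly 0 and empty classes
  contribute 0.
* The lesion-weighted binary variant (`weighted_dice_loss`) implements
  the 1:3 prediction:truth denominator weighting,
  $1 - 4\sum pt / (\sum p^2 + 3\sum t^2)$, the factor 4 renormalizing
  so a perfect prediction still scores 0.  It penalizes
  under-segmentation of the lesion more than over-segmentation, and
  equals the plain binary Dice loss exactly at perfect prediction.
* Undefined classification rates (zero denominators) are reported as
  `NA`, never silently 0, so averages cannot be inflated.
* Sensitivity and specificity are implemented with their standard
  definitions ($TP/(TP+FN)$, $TN/(TN+FP)$).  The printed formulas in
  the source description use $TP+FP$ denominators for both, which
  duplicates precision and contradicts standard usage;
  `paper_exact = TRUE` reproduces them verbatim for comparison.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `num_blocks` (T) | attention blocks | 8 | the published block count is not credibly parseable; 8 is desk-scale trainable, tests use 2 |
| `width` (w) | feature channels | 64 | published tuning settles on 64; tests use 8–16 |
| `reduction` (h) | MLP bottleneck ratio | 4 | keeps the hidden width ≥ 4 at the test width 16 |
| `leaky_slope` | negative slope α | 0.2 | unspecified in the source; any small positive slope preserves signed coefficients |
| `downsample_factor` | baseline factor s | 2 | unspecified; 2 keeps the baseline informative |
| `wavelet` | filter pair | haar | simplest orthonormal filter with exact closed forms; `db2` selectable |
| `lr` | Adam step size | 1e-3 | no optimizer/schedule is published; Adam 1e-3 is the field default |
| `lambda` | L2 coefficient | 1e-4 | regularization named but never defined; standard small value |

Biases are included in every convolution and in the MLP (initialized to
zero) even though the published notation omits them for brevity.
Weights are Kaiming-uniform from the config seed; runs are bitwise
reproducible.

## Numerical and implementation choices

* **Wavelet transform.**  Implemented as multiplication by orthonormal
  periodized analysis matrices (rows: shifted low/high-pass filters).
  Orthogonality gives perfect reconstruction, exact energy
  conservation, and makes the IDWT adjoint equal the DWT — which is
  exactly the gradient the reconstruction loss needs.  Odd dimensions
  are replicate-padded to even; the pad is recorded and stripped on
  inversion.  Coefficient channel order is fixed as (LL, LH, HL, HH) in
  memory and on disk.
* **Bicubic resampling.**  Keys cubic convolution, $a = -0.5$,
  half-pixel centers, clamped borders.  Scale 1 is the exact identity;
  constants and linear ramps are reproduced exactly away from clamped
  borders.
* **Convolutions.**  Same-padded (zero) im2col + BLAS matmul, batched
  over samples; the backward pass is the exact adjoint.  All wavelet
  and test arithmetic is double precision.
* **Pooling ties.**  Max-pooling gradients go to the first maximizer
  (`ties.method = "first"`), a deterministic subgradient choice.
* **Leaky-ReLU at 0** uses slope α, the negative-branch subgradient.
* **Gradient correctness** is enforced by a test comparing every
  parameter group against central finite differences on a tiny
  configuration, and by closed-form identities (zero-weight blocks are
  exact identities; a zeroed final fusion conv reproduces the baseline
  bitwise).

## The phantom generator

Real annotated tumor MRI cannot ship with the package, so all training
and testing runs on synthetic phantoms: concentric random ellipses
(outer = whole tumor, middle = tumor core, inner = enhancing tumor,
sharing center and orientation so the WT ⊇ TC ⊇ ET nesting holds by
construction) with per-class mean intensities, a background texture of
three seeded low-frequency cosine gratings (so the wavelet front end
sees nontrivial content in every band), and i.i.d. Gaussian noise.
Defaults: 64x64, two classes, means 0.2/0.9, noise sd 0.05, texture
amplitude 0.1; 240x240 is available to mirror clinical slice sizes.

What the phantoms do *not* emulate: MRI physics (bias fields,
multi-modal contrast relationships), irregular infiltrative tumor
shapes, partial-volume boundaries, and inter-subject variability.
Passing the desk-scale protocol therefore shows that the implementation
is correct and trainable — that the architecture can fit
nested-structure segmentation data deterministically — not that it
reaches clinical accuracy on real scans.

## The desk-scale protocols

The functional smoke test overfits 16 phantoms (64x64, two classes,
noise sd 0.05, seeds 0–15) with T = 2, w = 16, h = 4, Adam 1e-3, 200
full-batch epochs, and requires mean foreground Dice ≥ 0.90 on the
training set; it reaches ≈ 0.98 in about 3 minutes on one CPU.  The
width sweep repeats the identical protocol at w = 8 and w = 16 and
checks that reconstruction PSNR does not decrease with width (≈ 25.2 dB
→ ≈ 25.7 dB), the scaled-down analogue of the published
capacity-vs-quality trend.  Problem sizes were chosen so the whole
suite runs in minutes; both protocols are deterministic given their
seeds.

## Known limitations

* One 2D plane per call; multi-modal fusion is left to the caller as
  channel stacking, and no 3D variant is provided.
* The segmentation head is declared plumbing (see above); its placement
  on the fused features is one reasonable choice among several.
* Single-level DWT only; no multi-level pyramids.
* The pure-R engine favours transparency over speed: it is entirely
  adequate at desk scale but not a GPU-scale training system.
* NIfTI affines are passed through untouched; resampling/registration
  is out of scope.
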