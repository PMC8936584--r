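---
title: "Region-localized echocardiogram segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-localized echocardiogram segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative cardiac indices (chamber volumes, wall thickness, vena-cava
collapsibility) are read off segmentations of 2-D echocardiograms. Two things
make echo segmentation hard: the regions of interest occupy a small part of a
noisy, speckled frame, and neighbouring structures — especially the septal
wall (SW) and posterior wall (PW) flanking the left ventricle (LV) — are
thin, similar in texture and hard to separate. `echoseg` implements an
end-to-end network that first *localizes* each cardiac region with a spatial
transformer and then *segments* each localized crop with three concurrent
feature pathways, so segmentation capacity is spent on the region instead of
the background. Two view configurations are built in: a five-region
parasternal long-axis view (LV, SW, PW, RV, LA) and a single-region inferior
vena cava view.

## Model

**Coarse mask.** A compact FCN-8-style network (stride-32 VGG-like encoder,
skip fusion from the 1/8, 1/16 and 1/32 stages, upsampling back to full
resolution) produces a rough label mask `z`. Its only job is to tell the
localizer roughly where the regions are; it is deliberately small and is
trained first and then frozen.

**Localization.** The localizer `L` consumes the one-hot encoded coarse mask
(eight 3x3 conv/BN/ReLU layers, stride 2 on every second layer, global
average pooling, linear head) and regresses, per region, the four free
entries of a restricted affine transform

$$\theta = \begin{bmatrix} s_x & 0 & t_x \\ 0 & s_y & t_y \end{bmatrix},$$

i.e. scale and translation with shear fixed at zero — enough for cropping,
never flipping or shearing the anatomy. The grid generator maps the canonical
target grid through \(\theta\) (`make_sampling_grid()`) and a truncated-kernel
bilinear sampler

$$V_i = \sum_{n}^{H}\sum_{m}^{W} U_{nm}\,
  \max(0, 1-|x^s_i - m|)\,\max(0, 1-|y^s_i - n|)$$

interpolates the crop (`bilinear_sample()`). The kernel is differentiable in
both the image and the grid, so localization gradients flow from the
segmentation loss through the crop.

**Segmentation pathways.** Each region crop is processed by three parallel
branches sharing weights across regions:

* *Spatial pathway (SP)* — three 3x3 stride-2 conv/BN/ReLU blocks with 64,
  64, 128 filters; cheap, wide, captures low-level detail at 1/8 resolution.
* *Handcrafted pathway (HP)* — three local-binary-convolution (LBC) blocks.
  An LBC block applies `m` *fixed* sparse anchor filters (entries in
  {-1, +1}, a configurable sparsity, drawn once from a seeded RNG), a ReLU,
  and a learnable 1x1 recombination:
  `y = conv1x1(ReLU(conv_anchor(x)))`. This is the convolutional re-casting
  of local binary patterns: the anchors compute signed neighbourhood
  differences, the ReLU binarizes softly, the 1x1 layer learns the code
  weighting. Only `m * c_out` weights per block are learnable — a `k^2`-fold
  reduction versus a standard `k x k` layer when `m = c_in` — and gradients
  flow *through* the anchors without ever updating them. Texture-sensitive
  and nearly free, this branch is what helps separate the look-alike walls.
* *Context pathway (CP)* — a lightweight depthwise-separable stack
  downsampling to 1/32, where global average pooling produces a 1x1 global
  descriptor that re-weights the 1/32 map; the result is projected and
  upsampled to 1/8. Class logits tapped at 1/16 and 1/32 provide auxiliary
  deep supervision.

**Fusion and head.** The three 1/8-resolution maps are concatenated,
batch-normalized (balancing their scales), and re-weighted by channel
attention: a pooled sigmoid bottleneck yields `w` in (0,1) per channel and

$$v_{\text{output}} = v_{\text{concat}} \cdot w + v_{\text{concat}},$$

so each channel is scaled by a factor in (1, 2) — a residual form of
squeeze-excitation. A 1x1 convolution and x8 bilinear upsampling produce
per-pixel class logits for the crop; `inverse_remap()` pastes the per-crop
argmax labels back to frame coordinates through \(\theta^{-1}\), resolving
multi-crop conflicts in favour of the crop whose sampling point is nearest
its own center (ties to the lower region id).

## Losses and training protocol

The segmentation loss per crop is mean per-pixel softmax cross-entropy plus
two auxiliary terms from the context pathway,
`L_seg = L_p + alpha1 * L_aux1 + alpha2 * L_aux2` with both weights
defaulting to 1; auxiliary logits are upsampled to label resolution first so
the weights are resolution-independent and thin-wall labels are never
coarsened. The network loss is the arithmetic mean of `L_seg` over the `N`
region crops. Crop-parameter regression uses the smooth-L1 loss
(quadratic inside |r| < 1, linear outside, continuous with matching
derivatives at the joint).

Training proceeds in two stages (`pretrain_coarse()`,
`pretrain_localizer()`, `finetune_end_to_end()`):

1. the coarse net is trained with cross-entropy (Adam, lr 1e-3, reduced on
   validation plateau, best-validation weights kept), then frozen;
2. the localizer is trained against ground-truth crop parameters
   \(\theta^{gt}\) under smooth-L1;
3. everything except the coarse net and the LBC anchors is fine-tuned
   jointly against the mean per-region segmentation loss.

\(\theta^{gt}\) is derived from the ground-truth mask as the tight axis-aligned
bounding box of the region expanded by a 10% margin per side and clipped to
the frame (`theta_gt_from_mask()`); the margin keeps wall pixels at the box
edge from being clipped by resampling.

**Two stabilizers in stage 2.** With small training sets, two pathologies of
joint training showed up in pilot runs and are countered by design:

1. *Crop inflation.* Because the segmentation loss is a *mean* over crop
   pixels, the localizer can lower it by inflating crops so that easy
   background pixels dilute the hard ones (crop-parameter error grew
   five-fold during fine-tuning while crop-level accuracy under correct
   crops collapsed). Fine-tuning therefore keeps the smooth-L1 term in the
   total loss (`theta_loss_weight`). Since that term is averaged over all
   `4 N` free entries, its gradient is an order of magnitude smaller than
   the segmentation gradient reaching \(\theta\) through the sampler; the
   default weight of 10 restores commensurate scales. The localizer remains
   fully trainable end-to-end — it receives gradients both from the sampler
   and from this anchor — and weight 0 restores the pure segmentation
   objective.
2. *Normalization mismatch.* At the small fine-tuning batch sizes used
   here, the localizer's batch-norm statistics computed per batch differ
   substantially from the running averages used at inference, so the
   \(\theta\) being trained is not the \(\theta\) being deployed — and the
   pathways then see crops at inference that they were never trained on.
   During stage 2 the localizer therefore runs with its stage-1 running
   statistics (weights still trainable, gradients unchanged); the pathway
   batch norms keep normal batch statistics, since each step already
   batches `N` crops.

Defaults follow the full-scale protocol: batch 16, Adam at 1e-3, 100
fine-tuning epochs, plateau reduction factor 0.5 with patience 5, and
on-the-fly augmentation drawing rotation in [-15, 15] degrees, shifts in
[-0.25, 0.25] of the frame, scale from {0.75, 1, 1.25} and both flips, with
the identical geometric transform applied to the image (bilinear) and mask
(nearest). Datasets are split subject-wise 20/60/20 into coarse-training,
fine-training and test sets so no patient leaks across splits.

## The synthetic phantom generator

No public dataset exists for these views, so `generate_phantom()` renders
parametric phantoms that reproduce the *geometry and nuisance structure* of
echo frames: a dark background with a bright cone-shaped imaging sector;
dark blood pools with bright rims for the chambers; thin bright ribbons
(at most 8% of the frame height) hugging the LV for the septal and posterior
walls, preserving the thin-wall difficulty; multiplicative unit-mean gamma
speckle (shape 4, a standard ultrasound speckle surrogate — contrast stays
geometry-driven because the noise is unit-mean); and mild blur. The IVC mode
renders one elongated bright-walled tube. `generate_dataset()` adds subject
structure: a larger geometry jitter between subjects (centers +-2.5% of the
frame, sizes +-8%, orientations +-6 degrees) and a smaller one between frames
of a subject (+-0.8%, +-3%, +-2 degrees), mimicking consecutive video frames,
with subject ids for subject-wise splitting.

What the phantoms do *not* emulate: B-mode point-spread physics (polar-grid
PSF convolution, attenuation, shadowing), probe-dependent gain maps,
pathology, or out-of-plane motion. Passing tests on phantoms therefore
demonstrates that the architecture, gradients and training protocol work as
specified — not clinical-grade accuracy on real echocardiograms.

## Numerical choices

* **Coordinates.** All grids use the align-corners convention: (-1,-1) is
  the *center* of the top-left pixel, (+1,+1) of the bottom-right. The
  identity \(\theta\) is then an exact identity map, which the tests exploit.
* **Sampling.** Out-of-frame source coordinates contribute zero (the
  truncated kernel). Label maps are always resampled nearest-neighbour;
  bilinear interpolation is reserved for intensities and features.
* **Localizer head.** Initialized near the identity transform (bias
  `s = 1, t = 0`, small random weights) so early training cannot collapse
  crops; predicted scales are clamped to [0.05, 1.5] to keep
  \(\theta^{-1}\) well-defined.
* **LBC anchors.** Drawn once from a configurable seed; sparsity defaults to
  0.5 with `m = 2 c_in` anchors per block; stride-2 in the anchor
  convolution provides each block's spatial reduction.
* **Coarse mask input.** `z` enters the localizer as one-hot argmax labels
  (not probabilities), so the localizer is insensitive to label magnitude.
* **Batch norm.** Population statistics over (H, W, batch) during training
  with momentum 0.1 running averages for inference; inference is therefore
  batch-independent.
* **Differentiation.** The package carries its own reverse-mode engine
  (compiled im2col/col2im convolutions, depthwise kernels, the bilinear
  sampler with analytic image/grid gradients, batch-norm and cross-entropy
  kernels); every backward pass is verified against central finite
  differences in the test suite.

## Scaled-down study conditions

The full-scale configuration (512x512 frames, crops at the working
resolution, batch 16, 100 epochs) is impractical for routine testing, so the
package's experiments run at a desk scale stated here: 128x128 frames with
96x96 region crops — pilot decompositions showed the thin walls are limited
by the 1/8-resolution prediction grid, and 96 is the smallest stride-32
multiple whose feature grid resolves them while keeping training quick on a
single CPU — fine-tuning batch 1 (each step already batches the N = 5
region crops, and small batches give 3-10x more optimizer steps on 30-50
frames than the full-scale batch of 16 would), 12-15 pre-training epochs,
30 fine-tuning epochs, and
augmentation disabled for determinism of the scaled-down runs. The
crop-parameter recovery experiment trains on 50 phantoms and evaluates on
held-out subjects; the end-to-end experiment trains on 30 phantoms and
evaluates mean IoU over the five regions on held-out subjects. Unit tests
use 64x64 frames with 32x32 crops.

## Known limitations

* Phantom realism is topological, not photometric; results do not transfer
  claims to clinical data.
* At desk scale the 1/8-resolution prediction grid is coarse relative to the
  wall ribbons; wall IoU is the binding constraint on the aggregate score.
* The remap pastes *all* labels a crop predicts (with the center-distance
  tie-break); a crop may claim pixels outside every other crop's footprint.
* One shared head serves all regions; per-region binary heads are not
  implemented.
* Non-affine (projective/thin-plate) localization and multi-transformer
  cascades are out of scope.
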