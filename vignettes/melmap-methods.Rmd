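---
title: "Patch-based melanoma recognition in whole-slide images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based melanoma recognition in whole-slide images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Malignant melanoma is diagnosed from hematoxylin–eosin (H&E) stained
pathology slides scanned into whole-slide images (WSIs) of billions of
pixels. Pixel-wise segmentation networks do not scale to such images, and
downsampling destroys the cell-level morphology on which the diagnosis
rests: malignant regions show enlarged, darkly stained nuclei with
irregular shapes. `melmap` implements the patch-based alternative: break
the slide into fixed windows, classify each window as benign or
malignant with a convolutional network, and reassemble the per-patch
probabilities into a slide-level probability map from which a mosaic
lesion mask and lesion regions are derived.

## Pipeline

1. **Tiling.** A sliding window (default 1024 px, stride 1024 px) crops
   patches at every position `(r·stride, c·stride)` that fits inside the
   slide. With stride < window the sampling overlaps, which avoids losing
   cells torn at patch borders; the patch-count formula
   `floor((H−w)/s+1) · floor((W−w)/s+1)` holds either way. Partial border
   windows are dropped by default (an optional zero-pad mode keeps them).
2. **Tissue filtering.** Slides are mostly glass. A window is kept when
   at least 10% of its pixels have HSV saturation above 0.05: glass is
   near-white (saturation ≈ 0) while stained tissue is strongly
   saturated. Both constants are exposed; the rule is deliberately the
   simplest colour analysis that separates the two.
3. **Multi-scale cropping.** Each patch yields six images: the whole
   patch plus five half-side sub-patches (four corner quadrants and one
   centred crop — a symmetric layout that covers every pixel twice). All
   six are resized to the network input (default 512 px) and scaled to
   [0, 1]; this is the second, finer scale at which nuclear morphology is
   presented to the network.
4. **Classification.** The six images pass through a shared-weight
   network (below); their penultimate feature vectors are averaged and a
   single sigmoid unit outputs the malignancy probability. A patch is
   called malignant when the probability is ≥ 0.5 (inclusive).
5. **Probability map.** Predictions are placed on the tile grid; cells
   hit by several predictions (overlapping tilings) average. Cells with
   no prediction — background filtered out — hold probability 0: glass is
   never lesion. Thresholding the map (default 0.5, inclusive) gives the
   mosaic mask; 4-connected components of positive cells become lesion
   regions with pixel bounding boxes and mean probabilities.

## The network

The classifier is a bottleneck/basic residual network (depths 18, 50,
101) with three modifications, each independently switchable so that
every ablation row of the design space is a reachable configuration:

**Deformable convolution.** The 3×3 convolution of a residual block may
be replaced by its deformable counterpart,

  y(p) = Σₖ w(pₖ) · x(p + pₖ + Δpₖ),

where the offsets Δpₖ (a (dy, dx) pair per kernel tap per output
position) are predicted by a parallel standard convolution, clamped
elementwise to ±2 (the maximum resampling distance), and resolved by
bilinear interpolation with zero outside the map. The offset-predicting
convolution is zero-initialized, so a freshly built network is exactly a
plain CNN and the irregular sampling is learned, not imposed. This suits
lesions whose boundaries defeat a fixed rectangular receptive field.

**Channel attention.** A squeeze-excitation gate

  Y = σ(W₂ δ(W₁ · mean_{i,j} X(i,j))) ⊗ X

re-weights channels by gains in (0, 1) computed from globally pooled
features (δ = ReLU, σ = sigmoid; reduction ratio 16 by default, the
standard squeeze-excitation setting). It can be placed inside every
residual block ("backbone"), on each branch feeding the fully connected
head ("shortcut"), both, or neither.

**Multi-scale feature fusion.** The stage outputs F_Conv2..F_Conv5 form a
pyramid. Enabled branches compute
F_i = concat(BN(up₂(conv₁ₓ₁(F_{i+1}))), BN(F_Conv_i)) — a 1×1 lateral
convolution, ×2 bilinear up-sampling and channel concatenation, with
per-group batch normalization so neither group dominates the concat.
Branches form a contiguous suffix (F5 only; +F4; +F4/F3; +F4/F3/F2),
matching the ablation order of the design. Every enabled branch map is
globally average-pooled, the vectors are concatenated and passed through
a fully connected layer of width 1024 (the penultimate representation
exported for embedding diagnostics), then the final sigmoid unit.

Decisions the method statement leaves open, fixed here as package
choices: the six images share one backbone and are combined by averaging
their penultimate vectors (a concatenation mode exists behind a flag);
"flattening" of branch maps is global average pooling, since a raw
flatten of a 128×128 map is infeasible at full scale; the lateral 1×1
convolution outputs as many channels as the stage it joins; the head is
a single sigmoid unit rather than a 2-way softmax, matching the sigmoid
binary cross-entropy loss.

## Training

Sigmoid binary cross-entropy (computed from logits for numerical
safety), SGD with momentum 0.9, learning rate 0.001 multiplied by 0.99
after every epoch, 30 epochs, batch size 32, and a stratified 6:2:2
train/validation/test split are the full-scale defaults. Training images
are augmented by an independent horizontal-mirror coin flip and a
rotation drawn uniformly from the open interval (−90°, +90°);
melanoma texture is non-directional, so both are label-preserving.
Rotation fills exposed corners by reflection rather than black, so the
classifier cannot key on rotation artifacts; augmentation is applied
independently to each of the six images of a patch. All randomness —
initialization, shuffling, augmentation — derives from one recorded
seed, and a rerun reproduces the epoch-loss trace exactly (single-thread
BLAS). Evaluation reports precision, recall, accuracy and
F1 = 2PR/(P+R) with malignant as the positive class; a zero denominator
is reported as 0 with a flag, never NaN.

The deep-learning stack itself — convolution via im2col/GEMM, batch
normalization, pooling, the deformable sampler with its gradients
(including gradients through the bilinear weights to the offsets), and
back-propagation through the fusion pyramid and grouped head — is
implemented in this package with compiled kernels, and is verified
against independent nested-loop oracles and finite-difference gradient
checks in the test suite.

## The synthetic-slide generator

Clinical WSI datasets with expert labels are scarce and private, so the
package ships a seeded generator that emulates the features this method
actually uses: a near-white background (RGB ≈ 245), elliptical tissue
blobs of eosin-pink stroma, and per-class nucleus textures drawn as
anti-aliased ellipses with radial boundary perturbation. Malignant
regions differ from benign ones exactly along the axes pathology
describes — larger radius (mean 10 px vs 7 px at the reference scale),
darker stain (blend 0.80 vs 0.55 toward hematoxylin purple), higher
eccentricity (0.55 vs 0.25), stronger boundary irregularity (0.25 vs
0.05) and higher density (8×10⁻⁴ vs 6×10⁻⁴ per px²). Gaussian pixel
noise (sd 2.5 on the 8-bit scale) is added last. Ground truth is a
per-pixel region mask; a patch is labelled malignant when its tissue
fraction is at least 0.10 (the tissue-filter default — a near-empty
window is never labelled malignant) and at least half of its tissue
pixels are malignant. Lesion ellipses are concentric with tissue blobs,
so lesions never touch glass.

What the generator does **not** emulate: stain variability between
laboratories, scanner artifacts, nuclear chromatin texture, inflammatory
infiltrate, or the genuinely ambiguous nevus-versus-melanoma morphology
that makes the clinical task hard. Passing the desk-scale recovery tests
therefore shows that the implementation is correct and trainable — that
gradients flow, the multi-scale pipeline is wired soundly, and the map
reassembly is exact — not that the model reaches clinical accuracy;
that claim requires expert-labelled clinical WSIs, which no synthetic
stand-in can replace.

## Desk-scale study conditions

The acceptance computations (`scripts/acceptance.R` and the end-to-end
test) use problem sizes a single CPU handles in minutes, chosen once as
the package's desk-scale reference: a depth-18 backbone at base width 8
with 64-px inputs, deformable convolution in Conv5, channel attention in
both placements and all three fusion branches; 600 single-class patches
(balance 0.5) rendered at 256 px; 8 epochs at batch size 32 with
learning rate 0.01 (a small-model choice — the full-scale default stays
at 0.001, but a width-8 network on a separable task trains in far fewer
steps at the higher rate); and a 4096×4096 synthetic slide tiled at
window 256, stride 256, whose window scales with the model input the
same way the full-scale 1024-px window relates to 512-px inputs. The
channel-attention reduction ratio is 4 at these widths so the squeezed
representation never collapses below two channels.

## Numerical choices and edge cases

* Resizing is half-pixel-centre bilinear; downscales are antialiased by
  an integer-factor box prefilter. Constant images are exactly preserved.
* Bilinear sampling in the deformable kernel reads zero outside the map;
  offset gradients are masked where the offset sits at the clamp.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.9, eps 1e-5) at inference; running state is
  saved in checkpoints.
* Thresholds are inclusive (≥) everywhere — patch labels, the map
  threshold, the tissue filter — so a probability of exactly 0.5 is
  malignant and grid/mask round trips are exact.
* The functional `fuse_features()` applies no normalization by default
  (so constants survive concatenation, which the trivial checks rely
  on); the trained network path always normalizes per group.
* Connected components are 4-connected — the conservative reading; two
  diagonal cells are two regions.
* Stratified splitting apportions each class by largest remainder, so
  every split is within one record of its exact fraction per class.

## Limitations

Training at full scale (depth-50/101, 512-px inputs, tens of thousands
of patches) is out of reach for a CPU-bound R implementation; the
package targets method-level correctness and desk-scale experiments.
Pyramidal WSI formats are read at level 0 only; stain normalization and
annotation-polygon parsing are out of scope.
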