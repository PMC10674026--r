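---
title: "Methods: an unfolded kernel-estimation attention U-Net for retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an unfolded kernel-estimation attention U-Net for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Blood vessels in colour fundus photographs are thin, low-contrast, curvilinear
structures on a brightly and unevenly illuminated retina. Segmenting them
pixel-by-pixel is the first quantitative step in screening for diabetic
retinopathy, where vessel calibre, tortuosity and neovascularisation carry
diagnostic signal. `retseg` implements a complete patch-based segmentation
pipeline around a U-Net variant with three additions: densely connected
dropout blocks in place of plain convolution blocks, atrous channel attention
in the encoder, unfolded deep kernel-estimation (UDKE) refinement in the
decoder, and a multiheaded attention head with per-level feature attention
modules (FAMs) under deep supervision.

## Model

**Backbone.** The encoder has `levels` (L) resolution stages. Each stage is a
dense dropout block followed by atrous channel attention and (except at the
bottleneck) 2×2 max pooling. A dense block with `dense_layers` (D) layers and
growth `growth` (j) feeds layer *d* the concatenation of the block input and
all previously produced maps — `F + (d−1)·j` channels — and emits `j` new maps
through batch normalisation → 3×3 convolution → ReLU → dropout; the block
output concatenates input and all `D·j` growth maps, so with the default
`F = 48, j = 12, D = 4` a block emits `F + 48` maps. The decoder mirrors this:
a stride-2 transpose convolution (halving the channel count — a choice made
for parameter economy; the channel width of this layer is otherwise
unconstrained), concatenation with the skip connection, a dense block, and a
UDKE block.

**Atrous channel attention.** Global average pooling reduces each feature map
to one scalar per channel; two parallel 1-D convolutions along the channel
axis — one plain, one dilated by `att_dilation`, both with kernel
`att_kernel` and zero padding — are summed and squashed by a logistic
function into per-channel weights in (0, 1) that rescale the block output.
Summation of the two branches is our choice; the branch combination is
otherwise unspecified, and summing keeps the module parameter-free beyond the
2k taps.

**UDKE.** Each block unrolls `udke_iters` (T) iterations of a
restoration-style update: iteration *t* estimates a multiplicative gain
`G_t(x)` and an additive residual `R_t(x)` with two small subnets and applies
`x ← G_t(x) ⊙ x + R_t(x)`. The multiply-then-add structure is the minimal
form consistent with per-iteration kernel estimation followed by residual
correction; with neutral subnets (G ≡ 1, R ≡ 0) the block is exactly the
identity, which the tests assert. Each subnet is a 3×3 convolution to
`udke_hidden` channels, a ReLU, and a 1×1 expansion back — a bottleneck kept
deliberately small because the blocks sit on full-width decoder features.

**Multiheaded attention head.** Every decoder level's features are lifted to
input resolution by bilinear interpolation. Per level, a 1×1 coarse head
predicts an auxiliary map; the concatenation of all upsampled decoder
features (the fused tensor) and the level features enter a FAM: an additive
attention gate (1×1 projections, sum, ReLU, 1×1, logistic) yields a spatial
attention map in (0, 1); the gated features are concatenated with the level
features and passed through 3×3 and 1×1 convolutions with a final logistic to
give the refined map. The final segmentation is the elementwise mean of the
refined maps — an exact invariant of the forward pass.

**Objective.** With L levels there are L−1 coarse and L−1 refined maps. The
loss is `Σ α_l·BCE(coarse_l) + Σ β_l·BCE(refined_l) + γ_f·BCE(final)`, each
term a mean binary cross-entropy over FOV pixels (predictions clipped at
1e−7). No weight values are prescribed anywhere upstream, so the package
defaults to `α_l = β_l = 0.25, γ_f = 1`, letting the final map dominate while
keeping gradient flow to every head; all weights are configurable.
Optimisation is Adam (default learning rate 1e−3, batches of 4 patches).

## Preprocessing

Images are reduced to one intensity plane (green channel by default — the
channel with the best vessel/background contrast in fundus photography;
Rec.601 luminance is available), standardised to zero mean and unit variance
(statistics over FOV pixels when a mask is present, an upstream ambiguity we
expose as an argument), mapped affinely onto [0, 255], passed through CLAHE
and a gamma correction. CLAHE uses a 256-bin histogram per tile, a clip limit
expressed as a multiple of the uniform bin height (default 2.0 over an 8×8
grid — community-standard fundus settings), excess redistributed uniformly,
and bilinear interpolation between the four surrounding tile mappings; with a
1×1 grid it reduces exactly to global clipped histogram equalisation, which
is how it is tested. Gamma defaults to 1.2 (mild brightening; unconstrained
upstream). FOV masks, when absent, are synthesised by thresholding, keeping
the largest connected component, closing and hole filling.

Augmentation applies one of five fixed operations — horizontal flip, vertical
flip, 90° counter-clockwise rotation, central 0.8× zoom, (+10, +10) pixel
shift — identically to image and masks, re-binarising masks and re-imposing
vessel ⊆ FOV containment.

**Patching.** Training draws random patches whose centres lie inside the FOV
(the regular grid is only specified for testing; random FOV-centred sampling
is standard practice). Inference tiles the image with `patch_size` windows at
`test_stride` (defaults 256 and 20), clamping the final origin per axis to
the image border so coverage is complete, and averages predictions over
overlaps; extract→stitch is an exact round-trip identity for any valid
geometry. Images smaller than a patch are reflect-padded and cropped back.

## The synthetic phantom

The generator emulates what the pipeline needs from a fundus photograph: a
circular FOV on a dark background, a red-dominant retina with a radial
illumination falloff, additive Gaussian noise, and a branching tree of
vessels that are darker than their surroundings, attenuating mainly the green
channel. Vessels grow as recursive biased random walks: `n_trees` stems start
near the disc centre heading outward; each segment of ten 1.5-px steps
jitters its heading (σ = 0.12 rad) and tapers slightly; with probability
`branch_prob` a segment bifurcates into two children at ±0.35–0.8 rad with
width scaled by 0.75, stopping below `width_min` or at the FOV rim. Rendering
stamps anti-aliased discs along the walk; the binary mask is the rendering
thresholded at 0.5, so mask and image correspond exactly. Default parameters
(256², three trees, branch probability 0.4, root half-width 4 px, 55%
vessel contrast, 25% shading, noise σ = 4) give vessel densities around
6–8% of the FOV, in the range of real fundus annotations.

What the phantom does **not** model: lesions (microaneurysms, exudates,
haemorrhages), the optic disc and macula, vessel central reflexes, JPEG
artefacts, and inter-image colour variation. Passing the synthetic suite
therefore demonstrates that the implementation is correct and trainable, not
that the architecture reaches its published accuracy on DRIVE/STARE/CHASE_DB1
— that would require the real datasets and full-scale training, which are out
of scope here.

## Numerical and engineering choices

All tensors are dense double-precision arrays in `[H, W, C, N]` layout.
Convolutions are lowered to one BLAS GEMM per kernel tap against a
zero-bordered shifted copy of each sample (no im2col materialisation; the
package keeps an explicit im2col/col2im pair purely as an independent oracle
in the tests). Gradients are exact reverse-mode derivatives on an operation
tape; every operator is verified against central finite differences, and the
whole network's worst parameter-gradient error on a micro configuration is
below 1e−6 relative. Batch normalisation uses batch statistics during
training (variance floor 0, ε = 1e−5, running-statistic momentum 0.1) and
running statistics at inference, so stitched predictions are independent of
patch batching order. OpenBLAS, when present, is pinned to a single thread at
load: the GEMMs are small and thread spin-up dominates. All randomness
(initialisation, patch sampling, dropout, phantom growth) flows from explicit
seeds; equal seeds give bit-identical checkpoints.

Degenerate inputs fail loudly: constant images cannot be standardised,
empty FOVs cannot be normalised or scored, single-class ground truth has no
ROC curve, and undefined metric ratios (e.g. precision with no predicted
positives) return `NA` with a warning rather than a silent 0.

## Problem sizes used by the test suite

Unit tests run a micro network (L = 2, F = 4, j = 2, D = 2, T = 1) on 8–16
pixel patches. The capacity experiment — also what `scripts/acceptance.R`
reruns — trains the small study configuration (L = 3, F = 16, j = 4, T = 2,
64-px patches, batches of 4, Adam at 1e−3) for 200 steps on eight 128²
phantoms and then evaluates on the same eight images with stride-20 stitched
prediction; the network is expected to drive the training loss below 10% of
its initial value and the training-set mean F1 above 0.9. These sizes were
chosen as the smallest configuration that still exercises every block of the
architecture end to end.

## Known limitations

* The published per-dataset accuracies are not reproduced here by design;
  the phantom study validates mechanism, not benchmark performance.
* The UDKE literature defines the unfolding via an explicit restoration cost;
  upstream only describes the structure qualitatively, so the
  multiply-then-add update here is one faithful instantiation, not the only
  one.
* Exactly five augmentations are fixed although only four families are named
  upstream; zoom and shift parameters are package choices.
* Training uses one random FOV-centred patch per augmented variant per epoch;
  other sampling schemes (e.g. fixed grids with balancing) are not
  implemented.
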