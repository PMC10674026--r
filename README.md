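# retseg

Patch-based segmentation of blood vessels in colour fundus photographs, for
researchers in retinal image analysis who want a self-contained, fully tested
R implementation of an attention U-Net with unfolded deep kernel estimation
(UDKE) — including preprocessing, training, stitched whole-image inference,
and the standard evaluation metrics — that runs end to end on synthetic
fundus phantoms with exact ground truth, no dataset download required.

## The model

The network is a U-Net of `L` resolution levels whose convolution blocks are
densely connected *dropout blocks*: layer `d` of a block receives
`F + (d−1)·j` channels (the block input concatenated with all earlier growth
maps) and emits `j` new maps via batch-norm → 3×3 convolution → ReLU →
dropout, so a block with `D` layers emits `C + D·j` channels (with the
defaults `F = 48, j = 12, D = 4`: `F + 48`). Each encoder stage ends in
*atrous channel attention*: global average pooling to a per-channel
descriptor, two parallel 1-D convolutions along the channel axis (kernel `k`,
one dilated by `r`), summed and squashed to per-channel weights in (0, 1).
Decoder stages upsample by transpose convolution, concatenate the skip,
apply a dense block, and then a *UDKE block* that unrolls `T` iterations of

```
x ← G_t(x) ⊙ x + R_t(x)
```

with learned multiplicative-gain and additive-residual subnets. Every decoder
level's features are lifted to input resolution; per level a 1×1 head gives a
coarse map and a *feature attention module* (additive attention gate +
refinement convolutions) gives a refined map. The final probability map is
the elementwise mean of the refined maps, trained with deep supervision:

```
L = Σ_l α_l·L_l^coarse + Σ_l β_l·L_l^refined + γ_f·L_f
```

where every term is a binary cross-entropy over field-of-view (FOV) pixels,
optimised with Adam in batches of 4 patches. Inference tiles the image with
256-px patches at stride 20 and averages overlaps.

The layers, their exact gradients, and the Adam optimiser are implemented in
R with small C++ BLAS kernels — no deep-learning framework is required.

## Worked example

```r
library(retseg)

# eight synthetic fundus phantoms with exact vessel + FOV ground truth
ds <- generate_dataset(8, phantom_params(height = 128, width = 128), seed = 9)

cfg <- run_config(
  network = network_config(base_channels = 16, growth = 4, dense_layers = 4,
                           levels = 3, udke_iters = 2, seed = 11),
  weights = loss_weights(3), patch_size = 64, max_steps = 200, seed = 5)

fit <- train(cfg, ds)
glance(fit)
#> # A tibble: 1 × 4
#>   steps initial_loss final_loss loss_ratio
#>   <int>        <dbl>      <dbl>      <dbl>
#> 1   200         2.89     0.0487     0.0169

ev <- evaluate(fit, ds)
glance(ev)
#> # A tibble: 1 × 6
#>   accuracy precision sensitivity    f1 jaccard   auc
#>      <dbl>     <dbl>       <dbl> <dbl>   <dbl> <dbl>
#> 1    0.995     0.981       0.974 0.977   0.956 1.000
```

The composite training loss falls to ~1.7% of its initial value in 200 steps,
and the stitched whole-image predictions recover the training phantoms'
vessel trees almost perfectly (mean F1 ≈ 0.98 inside the FOV) — the network
has enough capacity to learn the vessel appearance model, and every stage of
the pipeline (preprocessing, patching, forward pass, loss, optimiser,
stitching, metrics) is exercised on the way.

Confusion-matrix metrics follow the conventional definitions; for example a
matrix with TN = 58445, FP = 3603, FN = 3453, TP = 798 gives

```r
accuracy(cm)   # 0.8936 -> 89.4%
```

`autoplot(fit)` draws the loss curve, `autoplot(sample, "vessel")` shows a
phantom's ground truth, and `tidy()`/`glance()` return tibbles for further
analysis. A thin command-line wrapper lives in `inst/cli/uau.R`
(`phantom`, `train`, `predict`, `evaluate` subcommands).

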