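---
title: "Residual ECA-UNet++ segmentation of ultrasound lesions: models, phantoms, and compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual ECA-UNet++ segmentation of ultrasound lesions: models, phantoms, and compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultraseg)
```

## The problem

Segmenting tumors in B-mode ultrasound is hard for reasons intrinsic to the
modality: multiplicative speckle noise, acoustic shadows cast by strongly
attenuating structures, low lesion/background contrast, and boundaries
blurred by the imaging physics. `ultraseg` implements a complete,
CPU-testable pipeline for this task around a nested-U-Net ("UNet++")
segmentation network with a residual encoder and efficient channel
attention, the training protocol that goes with it, an exact metric
battery, and a model-compression stage (structured pruning + INT8
quantization) aimed at deployment on low-end hardware.

Because clinical ultrasound data cannot ship with a package, `ultraseg`
includes a deterministic synthetic phantom generator that reproduces the
statistical difficulties above. Every claim the test suite makes is made
on phantoms; the section on the generator below is explicit about what
that does and does not show about clinical images.

## The network

The model is a U-shaped encoder–decoder with dense nested skip
connections. Grid nodes are written $X^{i,j}$, where $i$ is the
downsampling level (row) and $j$ the skip-path depth (column):

$$
X^{i,j} =
\begin{cases}
H\!\left(X^{i-1,j}\right), & j = 0\\[4pt]
H\!\left(\left[\,[X^{i,k}]_{k=0}^{j-1},\; u(X^{i+1,j-1})\,\right]\right), & j > 0
\end{cases}
$$

with $H(\cdot)$ a convolutional submodule, $u(\cdot)$ bilinear ×2
upsampling, and $[\cdot]$ channel concatenation. With depth $L$ the grid
has $(L+1)(L+2)/2$ nodes and every node with $j>0$ receives exactly
$j+1$ inputs — the property `model_grid()` exposes and the tests assert
structurally. We realize $H$ as two (conv 3×3 → batch norm → ReLU)
blocks per node.

**Encoder.** The backbone column $X^{i,0}$ is a ResNet34-style residual
encoder: a 3×3 stem (the classical 7×7 kernel is replaced by 3×3 to
preserve small-target detail), batch normalization throughout, and four
stages of basic residual blocks (3, 4, 6, 3 blocks; widths
64/128/256/512 at `base_width = 64`). Each block is two 3×3
convolutions with an identity shortcut, or a projection shortcut where
stride or width changes. The stem is stride 1; a 2×2 max-pool performs
the first downsampling, and stages 2–4 downsample by stride-2 first
blocks, so a 512×512 input reaches a 32×32 bottleneck at $L=4$. The
stem stride and the decoder widths (32/64/128/256 top→bottom, i.e.
`base_width/2 · 2^i` per row) are conventions we fixed where the
architecture family leaves them open; both are configurable in
`model_config()`. A consequence worth stating: published parameter
totals for this architecture family cannot be reconstructed without
those choices, so `count_parameters()` / `count_flops()` report this
implementation's own accounting (FLOPs = 2 × multiply–accumulates of
all convolutions at a stated input size).

**Efficient channel attention (ECA).** After each encoder stage, features
are recalibrated per channel: global average pooling produces one
descriptor per channel, a 1-D convolution over the channel axis (zero
padded, no bias) mixes each channel with its $k-1$ neighbours, and a
sigmoid yields weights in $(0,1)$ that rescale the channels. The kernel
size adapts to the channel count,

$$k = \left|\frac{\log_2 C + b}{\gamma}\right|_{\mathrm{odd}},
\qquad \gamma = 2,\; b = 1,$$

where $|t|_{\mathrm{odd}}$ truncates to an integer and bumps even values
to the next odd number (never below 1) — the convention established for
this attention family; the defining papers print the formula but not
the rounding. So $C=64 \Rightarrow k=3$ and $C=256 \Rightarrow k=5$.
ECA is attention without dimensionality reduction: it adds only $k$
parameters per module. We place it on the encoder path only — the
encoder is where semantic abstraction happens and early channel
selection pays off, while re-weighting decoder features would interfere
with the high-resolution information carried by the skips — and leave
the decoder untouched.

**Deep supervision.** Each top-row node $X^{0,j}$, $j = 1..L$, carries a
1×1-conv + sigmoid head producing a full-resolution probability map.
During training the loss is averaged over all $L$ heads, which
shortens gradient paths to shallow layers; at inference the deepest
head is the output.

## Training protocol

`train_config()` defaults encode the protocol: batch size 8, AdamW
(decoupled weight decay $10^{-4}$ on convolution/attention weights
only), initial learning rate $10^{-3}$ under cosine annealing
$\mathrm{lr}(e) = \mathrm{lr}_{\min} + (\mathrm{lr}_0 -
\mathrm{lr}_{\min})(1+\cos(\pi e/E))/2$ to 0 over at most $E = 200$
epochs, and early stopping: training stops after 20 consecutive epochs
in which validation Dice failed to improve by more than $10^{-4}$
absolute (that threshold is our reading of "no significant
improvement"; it is configurable). The best-validation-Dice parameters
are checkpointed and restored. `early_stopping_trace()` replays the
bookkeeping on any metric sequence, which is how the protocol is unit
tested.

The loss is an equally weighted sum of pixel BCE and soft-Dice
complement, $\tfrac12\,\mathrm{BCE} + \tfrac12\,(1 - \mathrm{softDice})$
with additive smoothing 1 in the soft Dice (computed per sample,
averaged over the batch), averaged across supervision heads. The
protocol's source names deep supervision but no loss; BCE+Dice is the
standard pairing for Dice-scored binary segmentation and trains stably
at batch 8.

Data handling follows the 8:2 convention: `split_pairs()` partitions
`round(0.8 n)` pairs into training deterministically; a validation set
(10% of training, in our pipelines) is carved from the training split
because validation Dice drives early stopping and must be disjoint from
the test set. Splitting happens **before** augmentation so that
augmented copies of one image can never straddle the train/test
boundary. The three augmentations — horizontal flip, affine (rotation
±15°, isotropic scale 0.9–1.1, translation ±5%; ranges are our
conservative, configurable choice), and gamma contrast stretch (image
only) — are applied jointly to image and mask with nearest-neighbour
mask resampling, so masks stay strictly binary. The affine resampler is
implemented in the package (inverse mapping about the image center)
rather than through an external image library so that the identity
transform is exactly the identity and mask binarity is guaranteed by
construction.

## The phantom generator

`phantom_config()` / `generate_phantom()` produce image/mask pairs that
emulate, in order of the rendering pipeline:

1. **Irregular lesion geometry** — a star-convex region: an ellipse of
   random center, orientation, and axis ratio whose boundary radius is
   modulated by a smooth low-order Fourier series in the polar angle,
   amplitude set by `boundary_irregularity` (0 gives an exact ellipse).
   The draw is rejected and resampled (bounded retries) until the lesion
   area lies in `lesion_area_fraction_range`; the default 3–20% of the
   image skews small because small-object recognition is part of the
   difficulty being emulated.
2. **Hypoechoic contrast** — background level $b_0$ (default 0.65),
   lesion level $b_0(1-\text{contrast})$ with default contrast 0.35
   (a low-contrast regime); a hyperechoic flag inverts the polarity.
3. **Fuzzy boundaries** — Gaussian blur (default $\sigma = 2$ px) of the
   two-level field.
4. **Speckle** — pixelwise multiplicative factors from a unit-mean Gamma
   distribution with variance `speckle_strength` (default 0.3).
   Speckle in coherent imaging is multiplicative; Gamma is the standard
   positive unit-mean family with a single variance dial.
5. **Acoustic shadows** — with probability 0.3, a vertical band below a
   random row is attenuated by a factor decaying exponentially with
   depth, the simplest model of a shadowing structure; no ray tracing.

Determinism is strict: sample $i$ of a dataset with master seed $s$ uses
seed `phantom_sample_seed(s, i)` (a fixed affine rule modulo
$2^{31}-1$), so any sample can be regenerated in isolation and
`generate_dataset()` output is byte-identical across runs.

**What phantoms do not show.** No point-spread function, no RF-domain
physics, no anatomy, no operator variability, no annotation noise.
Passing the phantom benchmark demonstrates that the architecture,
optimizer, metrics, and compression machinery work as specified and
that the network can separate low-contrast, speckled, shadowed blobs
from background — it is evidence about the software and the method's
mechanics, not a claim of clinical performance.

## Metrics

All metrics are exact pixel computations, each cross-checked in the test
suite against an independent brute-force oracle:

* **Dice** $= 2|P\cap G| / (|P|+|G|)$. Both masks empty → 1.0 by policy
  (with a warning); exactly one empty → 0. These edge policies are ours;
  the definitions leave them open.
* **mIoU**: mean over the $k+1$ classes (here background + lesion) of
  $p_{ii} / (\sum_j p_{ij} + \sum_j p_{ji} - p_{ii})$ from the pixel
  confusion matrix; classes absent from both masks are excluded.
* **Accuracy, sensitivity, specificity** from TP/TN/FP/FN; undefined
  ratios surface as `NaN` with a warning, never silently.
* **Hausdorff distance** (max form, pixel units) between boundaries
  extracted as mask minus 4-connected erosion; empty-boundary images
  are excluded from averages and counted in the report.
* **ROC/AUC**: pixels pooled across the evaluation set, TPR/FPR at every
  distinct score threshold, trapezoidal AUC — equal to the concordance
  probability with ties counted ½, and invariant to monotone transforms
  of the scores.

`evaluate_masks()` reports both macro (per-image averaged) and pooled
(all pixels as one image) aggregates; macro is the default reporting
mode, pooled is exposed because the two differ and published tables
rarely say which was used.

## Compression

`prune_model()` performs one-shot structured pruning in the encoder:
output channels of each convolution are ranked by the L1 norm of their
kernels and the lowest 30% (default) dropped, keeping
$\max(1, \mathrm{round}(0.7\,C))$ channels. Channels meeting at residual
additions are coupled; they are pruned by the **union** of the kept sets
of all producing layers (block second convolutions and projection
shortcuts), so shortcut arithmetic stays valid — coupled interfaces may
therefore keep slightly more than 70%. Batch-norm parameters and
statistics, downstream input channels, and the decoder convolutions
that consume encoder rows are re-wired consistently, and each ECA
kernel size is recomputed from its new channel count. The output shape
contract is unchanged. One-shot pruning followed by a short low-rate
fine-tune is our default regime (iterative pruning is out of scope).
Because channel pruning removes whole fan-in slices downstream,
parameter reduction is super-linear in the channel fraction; the
efficiency report prints both channel and parameter reductions rather
than conflating them.

`quantize_model()` is post-training, per-tensor affine INT8: batch norm
is folded into the convolutions, every convolution weight tensor
(including ECA kernels) is stored as INT8 codes with one scale/zero
point per tensor (no FP32 conv weights remain; storage shrinks ~4×),
and activation ranges are calibrated as min/max of each convolution
output over a calibration set (16+ images suffice on phantoms).
Inference dequantizes weights from their codes and quantize–dequantizes
every convolution output against its calibrated range (simulated INT8
arithmetic). Per-tensor rather than per-channel scaling is chosen for
portability; the cost is a slightly larger quantization error on layers
with wide weight ranges. The worst-case weight round-trip error is
`scale/2`, i.e. ≤ 1/255 of the tensor's range.

## Numerical choices and degenerate inputs

* Convolution is im2col + GEMM in C++ (double precision); gradients are
  checked against central finite differences in the test suite.
* Batch norm uses biased variance, momentum 0.1, $\varepsilon=10^{-5}$;
  validation/prediction run on running statistics.
* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside BCE.
* Non-finite training loss aborts with a diagnostic rather than
  continuing.
* Inputs whose spatial size is not divisible by $2^L$ are rejected with
  the required multiple named.
* Ties in the L1 pruning ranking resolve by channel index (stable
  order); `fraction = 0` is an exact no-op.
* Masks are binarized at 0.5 after any resampling.

## Desk-scale problem sizes

The standing benchmark used by the test suite and the acceptance script
is sized for a single CPU: phantoms at 80×80 with the default
difficulty settings, 200 training / 20 validation / 50 test images,
`base_width = 8` (the architecture scales its widths, not its
structure), batch 8, and a cosine schedule over at most 8 epochs
(patience 7, as the early-stopping window must sit inside the epoch
budget). The overfit-capacity check uses one phantom at 64×64 and 300
optimizer steps. The ablation study (attention on vs off) runs 3 seeds
per arm at 48×48 with 48 training / 16 test images and 5 epochs;
pruning fine-tunes for 5 epochs at a third of the initial rate (the
test suite uses a 120-image training subset, the acceptance script the
full split). These sizes are this package's choices for a reproducible desk
run; the protocol defaults in `train_config()` (batch 8, lr $10^{-3}$,
200 epochs, patience 20) are the full-scale settings.

## Known limitations

* Single-lesion phantoms by default; multi-lesion scenes, anatomy-like
  backgrounds, and annotation disagreement are not modelled.
* The engine is CPU-only and double-precision; it is written for
  correctness and testability at desk scale, not for GPU-scale
  throughput.
* INT8 inference is simulated (dequantized arithmetic), so latency
  gains on integer hardware are not measured here; the efficiency
  report's latency column is explicitly local and hardware-dependent.
* Reported parameter/FLOP totals are specific to the stem/decoder
  conventions above and will not match published totals for sibling
  architectures that chose differently.
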