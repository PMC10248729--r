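---
title: "Methods: nuclei segmentation with a densely convolutional spatial attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclei segmentation with a densely convolutional spatial attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Nuclei segmentation assigns every pixel of a hematoxylin-and-eosin (H&E)
stained tissue image to *nucleus* or *background*. Hematoxylin stains
nuclei dark blue-violet and eosin stains cytoplasm and stroma pink, so
color carries most of the signal, but stain variability between
laboratories and scanners, noise, and densely packed nuclei make the task
non-trivial.

`dcsanet` implements an encoder-decoder convolutional network in the
U-Net family, with three additions over the plain architecture:

* **Parallel convolution blocks.** Each block runs a 5×5 and a 3×3
  convolution side by side on the same input, each followed by batch
  normalization and ReLU, and concatenates the two responses. A block
  with `k` filters per branch therefore outputs `2k` channels. The two
  kernel scales capture both coarse and fine texture from the same
  features.
* **A densely convolutional spatial attention module** after every
  encoder and decoder block. For an input map `F` (H×W×C):

  ```
  conv1   = ReLU(BN(conv3x3(F, dilation = D)))
  conv2   = ReLU(BN(conv3x3(conv1, dilation = D)))
  squeeze = ReLU(BN(conv1x1(F)))
  concat  = F ⊕ conv1 ⊕ conv2 ⊕ squeeze            # 4C channels
  fc1     = ReLU(mix(F))                            # width C
  fc2     = sigmoid(mix_bottleneck(concat))         # 4C -> C/r -> C
  out     = fc1 ⊗ fc2
  ```

  The sigmoid branch is a per-pixel soft gate on the ReLU branch; the
  dense concatenation lets the gate see the input together with two
  dilated-receptive-field views and a channel-squeezed view of it. With
  C = 256 channels and reduction ratio r = 8 the bottleneck has 32 units.
* **Channel attention on skip fusion.** Before a decoder feature map is
  concatenated with its encoder skip connection, its global-max-pooled
  channel vector passes through a dense layer and a sigmoid; the
  resulting per-channel weight rescales the decoder map.

Setting `use_parallel_block`, `use_dcsam` and `use_channel_attention` to
`FALSE` in `network_config()` recovers a plain U-Net, which is how the
ablation comparisons are built: the ablation lattice is strictly ordered
by trainable parameter count.

A 1×1 convolution plus sigmoid produces the per-pixel nucleus
probability. Input sizes must be divisible by `2^depth`.

### Interpretation choices in the attention module

The attention equations multiply the two channel-mixing branches
elementwise with the spatial maps, which forces both branches to retain
their H×W extent; "fully connected" is therefore implemented as 1×1
convolution (per-position channel mixing). The two 3×3 convolutions and
the squeeze each keep C output channels so the dense concatenation is 4C
wide without further conventions. Batch normalization is applied on the
three convolutional branches only, exactly where the equations place it.
No value is published for the dilation rate; the default is D = 2 on the
encoder side (where the receptive-field argument applies during
down-sampling) and D = 1 on the decoder side, both configurable.

### Other architecture defaults

Per-level channel widths are not published; the default is depth 4 with
`base_channels = 16` (bottleneck 256 for the plain block), a standard
U-Net scale that trains on a CPU at desk scale. Upsampling is
parameter-free 2× nearest-neighbour, matching the "2D-Upsampling"
description rather than transposed convolution. The skip tensor entering
channel attention is the encoder stage output (after its attention
module), not the raw network input — concatenating the raw input would
break channel arithmetic at inner stages. Weights are He-uniform
initialized and seedable; batch normalization uses momentum 0.99 and
epsilon 1e-3.

## The implementation

No deep-learning framework for R is assumed: the network is a
self-contained CPU implementation. Forward passes are recorded on a small
reverse-mode tape; every operator (convolution, fused batch-norm+ReLU,
pooling, upsampling, concatenation, attention gating) carries a
hand-derived backward rule, verified against finite differences in the
test suite. Convolutions avoid im2col entirely: each kernel tap is one
accumulating BLAS GEMM on the shifted (HW×C) feature matrix, with a
scalar fix-up along the zero-padding band, which keeps memory traffic at
the size of the feature maps. The package raises glibc's malloc mmap
threshold at load time because the training loop recycles many
multi-megabyte activation buffers.

## Pre- and post-processing

* **Stain normalization** (`stain_normalize()`): pixels are mapped to
  optical density (OD) by Beer–Lambert; tissue pixels (OD magnitude above
  β = 0.15) are projected onto the plane of their top-2 principal OD
  directions; the hematoxylin and eosin vectors are the 1st and 99th
  percentile angles (α = 1) in that plane; per-pixel concentrations are
  solved by least squares, clipped at zero, rescaled so each stain's 99th
  percentile matches the target maxima (1.9705, 1.0308), and recomposed
  with the reference stain matrix H = (0.65, 0.70, 0.29),
  E = (0.07, 0.99, 0.11). These defaults are the conventional ones for
  this algorithm family; all are configurable, and
  `stain_params_from_reference()` derives targets from a chosen reference
  tile instead. Hematoxylin is identified as the direction with the
  larger blue-channel OD component. Concentrations are solved by clipped
  least squares rather than sparse non-negative factorization — the
  latter belongs to a different normalization family. Blank tiles (too
  few tissue pixels) abort a single-image call with a typed error and
  pass through unchanged with a warning in batch mode.
* **Patch extraction** (`compute_grid()`, `extract_patches()`): 128×128
  windows at stride 64, 0-based row-major half-open coordinates, every
  window fully inside the tile; a 512×512 tile yields 49 patches, so the
  75-tile cohort yields 3,675 and six evaluation tiles yield 294.
  Trailing pixels beyond the last full window are dropped for
  non-conforming sizes.
* **Merging** (`merge_patches()`): overlapping patch predictions are
  fused per pixel by the arithmetic mean before thresholding — smooth and
  order-independent; max-fusion is available as an option. No published
  fusion rule exists for this step; the mean is this package's choice.
* **Post-processing** (`postprocess()`): binarize at 0.5, then delete
  8-connected components with pixel area < 30. The area rule is applied
  after merging, on full tiles. 8-connectivity is the conservative choice
  for speckle noise, which merges diagonally touching specks; the
  boundary is strict: area 29 is removed, area 30 kept.

## Training recipe

`train_config()` defaults: 100 epochs, batch size 8, Adam, training order
reshuffled every epoch from the seed, and a reduce-on-plateau schedule
monitoring validation loss — after 5 consecutive epochs without
improvement the learning rate is multiplied by 0.8. Choices this package
had to fix itself: initial learning rate 1e-3 (none is published for this
recipe); "improvement" means a decrease of at least 1e-4 absolute; a
floor of 1e-6 prevents underflow on long stagnation. Binary
cross-entropy is the default training loss, with soft Dice and soft
Jaccard losses selectable. The checkpoint with the lowest validation loss
is restored when training ends. The 80/20 train/validation split is at
patch level, matching the pipeline's published patch arithmetic
(3,675 → 2,940/735); this leaks tile context between the splits, so a
tile-level split can be had by splitting tiles before patching.

## Evaluation

Accuracy, Dice and Jaccard are computed per patch on thresholded
predictions (threshold 0.5; whether published scores use hard or soft
predictions is unstated, hard is the default here) and aggregated as mean
with a 95% percentile-bootstrap confidence interval over per-patch scores
(1,000 resamples, seeded; no CI method is published, the percentile
bootstrap over patches is this package's choice). Two empty masks score
Dice = Jaccard = 1 by ε-smoothing. `evaluate_model()` emits the same
report schema for the network and for the classical baseline.

## The classical baseline

A random-forest pixel classifier on a filter bank: raw gray intensity,
Gabor responses over frequencies {0.1, 0.2, 0.4} × orientations
{0°, 45°, 90°, 135°}, a Canny edge map, Sobel/Scharr/Roberts/Prewitt
gradient magnitudes, Gaussian blurs at σ ∈ {1, 2, 4}, and a 3×3 median —
defaults chosen here, as no filter parameters are published. The filter
list is described as "seven" types but names eight; all eight are
implemented. The forest has 100 trees, no depth cap, and training pixels
are subsampled balanced per class to keep memory at desk scale. Filter
convolutions use edge-replicate padding so uniform regions stay uniform
at borders.

## The synthetic tile generator

`generate_tile()` emulates what the downstream stages need from an H&E
crop: filled ellipses with random centers, semi-axes (4–12 px) and
rotation; a hematoxylin-like nucleus mean color (90, 60, 150) on an
eosin-like pink background (230, 180, 200); per-object color jitter
(SD 12) and additive Gaussian pixel noise (SD 8), clipped to [0, 255];
the paired mask is exactly the union of the rasterized ellipse interiors.
The default of 150–250 nuclei per 512×512 tile matches the annotation
density of the prostate dataset this pipeline was built around (above
16,000 nuclei across 75 tiles). With `allow_overlap = FALSE` nuclei are
rejection-sampled so components stay separate; otherwise overlapping
nuclei merge into one region, consistent with a generator that does not
model touching-nuclei boundary annotation. The generator does not model
chromatin texture, multiple tissue types, or annotation noise — passing
tests on it demonstrates that the pipeline's machinery is correct and
that the architecture can learn a color-plus-shape segmentation task, not
that it reaches any particular accuracy on real histology.

## Problem sizes used by the test suite

The suite verifies the deterministic pipeline counts at their natural
sizes (75/45/30/6 tiles of 512×512), runs metric and attention-module
oracle comparisons on small random inputs, and trains two kinds of
scaled-down models: a non-inferiority comparison of the full model
against its plain ablation (72 tiles of 32×32, 6 epochs), and a
learnability run of the full model (depth 3, base 8) for 30 epochs on 200
synthetic 64×64 patches, which must reach held-out soft Dice ≥ 0.80 — a
self-set floor demonstrating end-to-end learning, not a published number.

## Known limitations

* Batch normalization statistics during training are per-batch with
  running averages for inference; very small batches give noisy
  statistics.
* The merge step requires every pixel covered by at least one window;
  tile sizes that leave uncovered trailing pixels fail loudly rather than
  pad.
* Object-level metrics (aggregated Jaccard, panoptic quality) are out of
  scope; evaluation is pixel-level, as in the comparison tables this
  pipeline reports.
* Touching nuclei are not separated (no watershed step) — matching the
  pipeline's stated post-processing, which only removes small noise
  components.
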