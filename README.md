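# dcsanet

Binary nuclei segmentation of hematoxylin-and-eosin (H&E) histology tiles
with **DCSA-Net**, a U-Net-derived encoder-decoder carrying a densely
convolutional spatial attention module, parallel 5×5/3×3 convolution
blocks, and channel-wise attention on the skip connections — together
with the full pipeline around it: Macenko-style stain normalization,
overlapping sliding-window patch extraction and probability-map merging,
pixel-level evaluation with bootstrap confidence intervals,
connected-component post-processing, and a classical filter-bank +
random-forest baseline. A synthetic H&E-like tile generator makes every
stage testable without downloading any dataset.

The package is aimed at computational-pathology researchers who want a
transparent, dependency-light reference implementation of this
architecture family in R. The network is a self-contained CPU
implementation: forward passes are recorded on a reverse-mode tape,
every operator has a hand-derived backward rule (verified against finite
differences in the test suite), and convolutions run as tap-wise
accumulating BLAS GEMMs.

## The model

Each encoder/decoder block runs 5×5 and 3×3 convolutions in parallel
(each with batch normalization and ReLU) and concatenates the branches.
After every block, the spatial attention module gates the features: for
an input map `F ∈ ℝ^{H×W×C}`,

    conv1   = R[BN(f3×3(F, D))]
    conv2   = R[BN(f3×3(conv1, D))]
    squeeze = R[BN(f1×1(F))]
    concat  = F ⊕ conv1 ⊕ conv2 ⊕ squeeze
    fc1     = R[FC(F)]                       # width C
    fc2     = σ[FC(concat)]                  # 4C → C/r → C bottleneck
    out     = fc1 ⊗ fc2

with `R` = ReLU, `σ` = sigmoid, `D` the dilation rate and `r` the
reduction ratio (C = 256, r = 8 gives a 32-unit bottleneck). On the
decoder side, a sigmoid channel weight computed from the global-max-
pooled block output rescales the features before the skip concatenation.
A 1×1 convolution + sigmoid head emits per-pixel nucleus probabilities;
thresholding and removal of connected components smaller than 30 px give
the final mask. Ablation flags in `network_config()` switch each
addition off, recovering a plain U-Net.

Training follows a fixed recipe: Adam, batch size 8, per-epoch
shuffling, and reduce-on-plateau (validation loss, factor 0.8,
patience 5). Evaluation reports per-patch accuracy, Dice and Jaccard
(Eqs. below) with 95% percentile-bootstrap confidence intervals:

    Dice    = 2·Σ p·y / (Σ p + Σ y)
    Jaccard = Σ p·y / (Σ p + Σ y − Σ p·y)

## Worked example

```r
library(dcsanet)

# a small synthetic cohort: 64x64 H&E-like tiles with paired masks
spec <- synthetic_tile_spec(height = 64, width = 64,
                            n_nuclei_range = c(2L, 6L),
                            radius_range = c(4, 10))
tiles <- generate_dataset(120L, spec, seed = 7L)
split <- split_dataset(tiles, train_fraction = 0.8, seed = 1L)

model <- build_network(network_config(depth = 3L, base_channels = 8L),
                       seed = 1L)
model
#> DCSA segmentation network (depth 3, base 8)
#>   parallel block: TRUE | spatial attention: TRUE | channel attention: TRUE
#>   encoder block channels: 16, 32, 64
#>   bottleneck channels: 128
#>   decoder output channels: 128, 64, 32
#>   trainable parameters: 640733

state <- train_network(model, split$train, split$validation,
                       train_config(epochs = 12L, batch_size = 8L, seed = 1L))
tail(state$history[, c("epoch", "train_loss", "val_loss", "val_dice")], 3)
#>    epoch train_loss  val_loss  val_dice
#> 10    10 0.06205082 0.1983798 0.2493617
#> 11    11 0.04850477 0.1769086 0.5015455
#> 12    12 0.03957331 0.1556081 0.6464327

report <- evaluate_model(model, split$validation,
                         patch_size = 32L, stride = 32L, seed = 1L)
report
#> Metric report over 96 patches (mean, 95% bootstrap CI):
#>   accuracy   93.5% (92.3 - 94.7)
#>   dice       63.1% (56.4 - 69.1)
#>   jaccard    52.9% (46.5 - 59.1)
```

Twelve epochs take a few minutes on one CPU; the history shows the
validation loss still falling and the hard Dice score climbing steeply —
training to 30 epochs on a slightly larger cohort takes the held-out
soft Dice above 0.80 (that run is part of the test suite). The per-patch
accuracy/Dice/Jaccard means come with percentile-bootstrap intervals
over the evaluation patches.

For full-tile inference, `predict_tile()` runs the 128×128/stride-64
patch grid through the model and mean-fuses the overlapping predictions;
`postprocess()` binarizes and removes sub-30 px specks;
`colorize_overlay()` tints the segmented nuclei for visual inspection.
`fit_pixel_rf()` / `predict_mask_rf()` provide the classical
filter-bank + random-forest comparison through the same evaluation
pipeline.

A command-line front end wrapping these functions is installed at
`system.file("scripts", "dcsanet-cli", package = "dcsanet")` with
subcommands `synth-gen`, `stain-norm`, `patchify`, `train`, `predict`,
`evaluate`, and `describe`.

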