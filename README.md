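# mrisynth — intramodality brain MR contrast synthesis with a 2D U-Net

`mrisynth` synthesises one brain MRI contrast from another (T1 ⇄ T2 ⇄
FLAIR) by learning the nonlinear intensity mapping between co-registered
axial slice pairs. It is aimed at medical-imaging researchers who want a
fully inspectable, CPU-only, dependency-light implementation of the
standard slice-wise translation pipeline: phantom simulation →
preprocessing → U-Net training → slice-by-slice volume synthesis →
MAE/MSE/PSNR/SSIM evaluation with difference and SSIM maps.

## The method

A compact encoder–decoder convolutional network with skip connections maps
a 224×224 source slice x ∈ [0,1] to a target slice ŷ:

* encoder: 4 levels × (two 3×3 zero-padded stride-1 convolutions + ReLU,
  dropout after the first, 2×2 max pool), filters 16 → 128;
* bottleneck: two convolutions at 256 filters;
* decoder: mirror of the encoder with 2× nearest-neighbour upsampling and
  concatenation of mirrored encoder features;
* head: 1×1 convolution, tanh activation.

The canonical graph has **19 convolutional layers** and **1,962,337
trainable parameters** (≈ 2.0 M), counted analytically per layer as
(k_h·k_w·c_in + 1)·c_out and asserted equal to the instantiated network.
Training minimises MSE(ŷ, y) with Adam (lr 0.001, batch 32, He-uniform
initialisation) under early stopping on validation loss (patience 20),
keeping the best-epoch weights. Synthesis quality is scored with

* MAE = 1/n Σ|yᵢ − xᵢ|, MSE = 1/n Σ(yᵢ − xᵢ)²
* PSNR = 10·log₁₀(I²max / MSE) [dB]
* SSIM = (2μₓμᵧ + C₁)(2σₓᵧ + C₂) / ((μₓ² + μᵧ² + C₁)(σₓ² + σᵧ² + C₂))

aggregated as mean ± SD per translation direction. A seeded phantom
simulator (nested-ellipsoid anatomy, per-contrast tissue lookup tables,
bias field, noise, lesions) makes every stage testable without any
dataset download. See `vignettes/mrisynth-methods.Rmd` for the full
account of the model, parameters and design choices.

## Worked example

A toy end-to-end run (6 phantom subjects on a 32×32×16 grid, a reduced
depth-3 network, ~20 s on one CPU):

```r
library(mrisynth)

g <- build_layer_graph(unet_config())   # canonical 224x224 architecture
g$n_conv_layers
#> [1] 19
g$total_params
#> [1] 1962337

cfg <- run_config(n_subjects = 6, grid_shape = c(32, 32, 16),
                  n_null_slices = c(2, 2), slice_shape = c(32, 32),
                  depth = 3, base_filters = 4, max_epochs = 25,
                  batch_size = 16, steps_per_epoch = 12,
                  directions = "T1:T2", seed = 7)
res <- run_pipeline(cfg)
res$table
#>   Translation       PSNR_dB               MAE                 MSE              SSIM
#> 1      T1->T2 21.13 ± 2.834 0.04982 ± 0.02005 0.009225 ± 0.005634 0.9095 ± 0.03305

res$fits[["T1->T2"]]
#> U-Net translation model T1 -> T2
#>   25 epochs trained; best epoch 25 (val MSE 0.010023)
#>   7,465 trainable parameters
```

The table row is the held-out subject's slice-wise mean ± SD: the
synthetic T2 volume reaches 21.1 dB PSNR and 0.91 global SSIM against the
true (preprocessed) T2 — i.e. the network has learned the T1→T2 intensity
mapping well beyond the identity baseline even at this toy scale. Larger
phantom cohorts (8 subjects, 64×64×40, 20 epochs) reach ≈ 26 dB / 0.97
SSIM in a few minutes. `plot(res$fits[[1]])` draws the learning curves;
`save_panel_figure()` renders source / synthetic / truth / difference-map
/ SSIM-map comparison panels.

A thin command-line wrapper with `simulate`, `preprocess`, `train`,
`translate`, `evaluate` and `run-all` subcommands is installed at
`inst/cli/mrisynth`.

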