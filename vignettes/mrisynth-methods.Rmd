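---
title: "Cross-contrast brain MR synthesis with a compact 2D U-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-contrast brain MR synthesis with a compact 2D U-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisynth)
```

## The problem

A clinical brain MR examination ideally includes several contrasts of the
same anatomy — T1-weighted, T2-weighted and FLAIR — because each renders
tissue differently: T1 shows white matter brightest (WM > GM > CSF), T2
inverts that ordering (CSF > GM > WM), and FLAIR suppresses the CSF signal
so that lesions stand out. Acquiring all of them is not always feasible.
Because the contrasts are deterministic, tissue-dependent renderings of the
same underlying anatomy, a missing contrast can be *synthesised* from an
available one by learning the nonlinear intensity mapping between
co-registered image pairs. `mrisynth` implements that image-to-image
translation as a supervised regression with a compact 2D U-Net, trained
slice-by-slice on paired axial slices, together with everything around it:
a seeded multicontrast phantom simulator, volume preprocessing, a CPU
training harness, slice-wise volume synthesis, and image-quality
evaluation.

## The model

The network is an encoder–decoder with skip connections operating on
224×224 single-channel slices scaled to [0, 1]:

* **Encoder** — four resolution levels, each two 3×3 zero-padded stride-1
  convolutions with ReLU, a dropout layer after the first convolution, and
  a 2×2 stride-2 max pool. Filters double per level from 16 to 128.
* **Bottleneck** — two 3×3 convolutions at 256 filters (with dropout after
  the first). A single-convolution bottleneck is sometimes drawn for this
  family of networks; only the two-convolution form is consistent with the
  19-convolution, ≈2.0 M-parameter architecture this package constructs,
  so that is the canonical topology here (see `?build_layer_graph`).
* **Decoder** — a mirror of the encoder with 2× nearest-neighbour
  upsampling in place of pooling (transposed convolutions are avoided to
  sidestep checkerboard artifacts), concatenation with the mirrored
  encoder features, and the same two-convolution blocks. Decoder dropout
  mirrors the encoder schedule (a flag disables it; parameter counts are
  unaffected).
* **Head** — a 1×1 convolution to one channel with tanh activation.

Dropout rises linearly from 10% to 30% across the five levels; a linear
schedule is the simplest interpolation of an "increasing rate" between
those endpoints. Weights are He-uniform initialised (fan-in scaled, the
standard choice for ReLU stacks); batch normalisation is absent.

`build_layer_graph()` describes this topology declaratively — every layer
with shapes and an analytic parameter count `(kh·kw·c_in + 1)·c_out` — and
`instantiate_network()` builds the executable network from the graph, so
the analytic and instantiated counts can be asserted equal (they are, at
1,962,337 parameters for the canonical configuration). The convolution,
pooling and upsampling forward/backward kernels are implemented in C++
(im2col + GEMM); the backward pass is validated against central-difference
numerical gradients in the test suite rather than against any external
framework.

Two details of the canonical configuration deserve a note. All hidden
convolutions use stride 1 with zero padding, which is what keeps each
level's resolution constant and leaves downsampling entirely to the
pooling path; stride-2 convolutions would collapse the input long before
the fifth level and contradict the padding rationale. And the tanh output
spans (−1, 1) while targets live in [0, 1]: the loss is computed on the
raw tanh outputs, and predictions are clipped to [0, 1] only at inference,
which reconciles the ranges without distorting gradients.

## Training

`train_model()` minimises the mean squared error with Adam (learning rate
0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-7 — the published defaults beyond the
stated learning rate), drawing a random batch of 32 slices per step, for
up to 120 epochs with early stopping on the validation loss at patience
20. The model returned is the one with the minimal validation loss, not
the last epoch's. MSE is preferred over MAE as the objective: it is
convex, cheap, and has a stable gradient for this regression.

`steps_per_epoch` defaults to one full pass (`ceiling(n_train /
batch_size)`) but is exposed as a knob: the reference training schedule
for this architecture corresponds to 36 gradient updates per epoch
regardless of cohort size, which matters for small cohorts where a natural
epoch is only a handful of updates. The package's own small-cohort
experiment (below) uses an intermediate 18 updates per epoch so that a
20-epoch budget supplies enough optimisation steps while staying within a
few minutes on one CPU.

Early stopping returns the first epoch whose best-so-far predecessor lies
`patience` epochs or more in the past; improvement means a strictly
smaller validation loss. All six translation directions (T1→T2, T2→T1,
T1→FLAIR, FLAIR→T1, T2→FLAIR, FLAIR→T2) are trained from scratch by the
same harness with one shared configuration.

## Preprocessing

`preprocess_subject()` applies, in order:

1. **Null-slice removal** — an axial slice is *null* when its fraction of
   nonzero pixels is below 1e-3 (a near-zero threshold rather than exact
   zero, robust to stray interpolation noise). A slice is retained iff it
   is non-null in *at least one* contrast of the subject, and the same
   retained set is applied to every contrast, preserving slice pairing.
   The per-subject union rule is a repository decision; a per-contrast
   rule could desynchronise pairs.
2. **Intensity standardisation** — z-score over the brain (nonzero)
   voxels of the whole subject volume using the population SD (divisor
   *n*; the convention is recorded so either reading is auditable),
   followed by an affine min–max rescale of the volume to [0, 1]. All four
   constants are kept in a `normalization_record`, making the transform
   exactly invertible. Rescaling is per subject volume, not per slice.
   Normalisation runs after null-slice removal so its statistics come from
   retained tissue only.
3. **Resizing** — each slice is resampled to 224×224 (configurable) with
   Keys cubic convolution (a = −0.5), then clipped to [0, 1] to control
   cubic overshoot. Resizing runs last so interpolated values stay on the
   normalised scale.

Z-scoring before min–max makes the pipeline invariant to a positive gain
change of the scanner (an affine intensity transform of the input), which
is the point of standardising across scanners.

The 64/16/20 train/validation/test split is two-staged — 80/20 into
development and test, then 80/20 of development into train and validation
— with round-half-up at each 80% stage and the remainder going to the
held-out side; it is seeded and reproducible, so all models see identical
validation and test subjects.

## The phantom simulator

Real multicontrast cohorts are large downloads with restrictive licences;
the package therefore ships a generator of brain-*like* phantoms that
reproduces exactly the data properties the pipeline depends on:

* perfectly co-registered contrasts (all rendered from one tissue label
  grid), skull-stripped with exactly-zero background;
* configurable all-background slice margins at the bottom and top of the
  stack (defaults retain roughly 100 of 155 slices, the proportion typical
  of skull-stripped clinical volumes);
* nested-ellipsoid anatomy — an outer grey-matter shell, a white-matter
  core, two ellipsoidal lateral ventricles — plus, with probability 0.6,
  a single ellipsoidal lesion straddling the WM/GM boundary, so cohorts
  mix lesioned and healthy anatomy;
* per-contrast mean tissue intensities from lookup tables on a [0, 1]
  scale honouring the radiological orderings above (FLAIR: CSF ≈ 0,
  lesion brightest — the standard radiological convention, adopted here
  because no quantitative per-contrast lesion appearance is prescribed
  anywhere);
* a smooth multiplicative bias field (coarse Gaussian grid, trilinearly
  interpolated; mean 1 over the brain, maximum fractional deviation 0.10,
  spatial scale 16 mm) emulating coil-sensitivity inhomogeneity, the
  variation that motivates intensity standardisation;
* additive zero-mean Gaussian noise, SD 0.02 on the LUT scale (≈ SNR 25:1
  for mid-grey tissue, a realistic magnitude for modern scanners). A
  Gaussian rather than Rician model suffices at this SNR, where the two
  are nearly indistinguishable away from the background (which is masked
  to zero anyway).

Everything is seeded: identical configurations give bit-identical
volumes, and subject *i* of a cohort uses `seed + i − 1`.

What the phantom does **not** emulate: MR physics (relaxometry, k-space
artifacts, partial-volume mixing), gyral/sulcal geometry, multi-site
scanner diversity, or realistic lesion texture. Consequently the
phantom-based tests demonstrate that the pipeline is *correct* (shapes,
pairing, normalisation, optimisation, metric computation) and that the
network can learn a cross-contrast mapping in the presence of bias and
noise — they do not certify clinical image quality on real data, whose
anatomy is far richer than nested ellipsoids.

## Evaluation

Four pixel-wise metrics compare a synthetic image y against its ground
truth x, both on the normalised [0, 1] scale (the truth is preprocessed
identically to the training targets for a fair comparison):

* MAE = mean |yᵢ − xᵢ|; MSE = mean (yᵢ − xᵢ)²
* PSNR = 10·log₁₀(I²max / MSE) in dB, with Imax = 1; identical images
  yield an infinity sentinel that is excluded from aggregates with a
  logged count rather than crashing all-correct toy runs
* SSIM = (2μₓμᵧ + C₁)(2σₓᵧ + C₂) / ((μₓ² + μᵧ² + C₁)(σₓ² + σᵧ² + C₂))
  with C₁ = (0.01·Imax)², C₂ = (0.03·Imax)², computed from whole-image
  statistics (population convention) — the *global* SSIM used for the
  summary tables, since the defining formula is written in image-level
  moments. The *windowed* SSIM (uniform 7×7 window, valid region only) is
  provided separately as `ssim_map()` for visual inspection panels, next
  to the signed difference map y − x.

`evaluate_direction()` computes all four per aggregation unit — per slice
by default, per subject volume optionally; which unit a published table
aggregated over is typically ambiguous, so both are available — and
reports mean ± SD. `report_table()` assembles six directions into the
standard results-table shape.

## The small-cohort experiment

The acceptance experiment trains T1→T2 on a cohort of 8 phantom subjects
on a 64×64×40 grid (4 + 4 null slices), a depth-5 network reduced to 8
base filters, 20 epochs × 18 steps, and evaluates on the held-out split
(2 subjects, 64 slices). These sizes keep the full run in single-digit
minutes on one CPU while leaving the learning problem non-trivial (bias
field and noise on, lesions present). Two properties are asserted: the
synthetic T2 must beat the *identity baseline* (the preprocessed T1 source
itself) in mean PSNR against the true T2, and its mean global SSIM must
exceed 0.85. Full-scale clinical results (hundreds of subjects, ~100
retained 224×224 slices each, 120-epoch schedules) are out of desk-scale
reach by design; the evaluation module nevertheless emits the same
six-direction mean ± SD report shape for any data supplied at that scale.

## Numerical choices and degenerate inputs

* Split sizes: round-half-up on each 80% stage; remainders go to the
  held-out side. Fewer than 5 subjects cannot be split.
* Normalisation: volumes with no nonzero voxel, or constant brain
  intensity (SD = 0), are rejected as degenerate rather than silently
  producing NaNs.
* Bicubic resampling: edge replication at borders; centre-aligned
  coordinate mapping; constants are reproduced exactly (the Keys kernel
  is a partition of unity), and outputs are clipped to the valid range.
* Max pooling tie-break: the first maximum in column-major block order
  receives the gradient.
* Early stopping needs a non-empty loss sequence; patience ≥ 1.
* Dropout uses inverted scaling at train time, so inference needs no
  rescaling.
* Determinism: every stochastic component (phantom draw, split, weight
  initialisation, batch sampling, dropout masks) consumes a caller-visible
  seed, and the RNG state is restored afterwards; two runs with one seed
  are bit-identical on a given BLAS.

## Known limitations

* Training is single-threaded CPU; the canonical 224×224 network is
  buildable and runnable but full clinical-scale training is impractical
  here — the package targets method correctness and small-cohort
  experiments.
* The phantom's simplicity means phantom SSIM/PSNR values are far better
  than anything achievable on real anatomy at equal compute; they are
  qualification evidence, not benchmarks.
* `translate_volume()` returns volumes at the network's in-plane
  resolution on the normalised scale; mapping back to native resolution
  and raw intensities is possible via the stored normalisation records
  but is left to the caller.
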