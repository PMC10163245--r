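---
title: "Two-stage latent diffusion for 3D medical image volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage latent diffusion for 3D medical image volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

Cross-sectional imaging (MRI, CT) produces 3D volumes, but most generative
modelling work targets 2D images. Synthesizing whole volumes directly in
voxel space is computationally prohibitive and ignores that most anatomical
information lives at a coarser scale than the voxel. voxgen implements the
two-stage answer: first compress volumes into a small discrete latent grid
with a vector-quantized adversarial autoencoder (VQ-GAN), then learn a
denoising diffusion probabilistic model (DDPM) on that latent grid. New
volumes are produced by running the diffusion chain backwards from pure
noise, snapping the result onto the learned codebook, and decoding.

The package is written so that every stage is exercisable on procedurally
generated 3D phantoms at desk scale (grids of 16^3 to 64^3) on a single
CPU; the same code paths scale to medical resolutions (e.g. 256 x 256 x 32)
given proportionate compute. No medical data ships with, or is required by,
the package.

## Stage 1: the 3D VQ-GAN

`fit_vqgan()` trains an encoder that reduces each axis of an (H, W, D)
volume by the compression factor `s`, producing a continuous latent grid
`z_e` of shape (H/s, W/s, D/s) with `k` channels. Each latent vector is
replaced by its nearest codebook entry (`quantize_latents()`; ties go to
the lowest index), and the decoder maps the quantized grid back to a volume
through a final `tanh`, matching the [-1, 1] input normalization.

Losses and their roles:

* **Reconstruction** (`reconstruction_loss()`): the default, dependency-free
  mode is mean absolute error plus one minus the multiscale structural
  similarity (`ms_ssim()`). A slice-wise perceptual mode is available but
  requires the user to supply a 2D feature extractor; no pretrained weights
  ship with the package.
* **Commitment** (`commitment_loss()`): mean squared distance between
  `z_e` and its quantized counterpart; gradients flow only to `z_e`,
  pulling the encoder toward the codebook (weight `lambda_commit = 0.25`).
* **Codebook**: entries are not trained by gradient descent. Each entry
  keeps an exponential moving average (decay 0.99) of the latent vectors
  assigned to it and is set to their running mean
  (`codebook_ema_update()`). The explicit codebook loss of the original
  formulation is therefore implicit in the EMA update.
* **Adversarial**: a slice-wise patch discriminator scores one random depth
  slice and a volumetric discriminator scores the whole reconstruction,
  both with the hinge loss, plus a feature-matching L1 term over their
  hidden layers. The adversarial weight is held at zero for the first 25%
  of training (warm-up), and the generator-side adversarial gradient is
  rescaled so its norm is `lambda_gan` times the reconstruction gradient
  norm at the decoder output — the adaptive balancing used in the VQ-GAN
  lineage. Without this rescaling the adversarial term destabilizes small
  fits.

Quantization is non-differentiable; the straight-through estimator
(`straight_through()`) copies the decoder-input gradient onto `z_e`
unchanged, which the training loop implements explicitly.

Every encoder/decoder stage is convolution (or transposed convolution) →
instance normalization → SiLU. The normalization is not cosmetic: without
it, fits with two or more downsampling levels (s >= 4) reliably collapse
onto a constant cohort-mean reconstruction and never recover — the fastest
initial loss reduction is "predict the mean", after which per-image
gradients are too weak to escape that basin. With instance normalization
the same fits converge smoothly at every compression factor.

A fitted model is an S3 object: `print()`, `summary()`, `plot()` (loss
curve), `predict()` (with `type = "reconstruction"`, `"latent"`,
`"quantized"`, `"indices"`) and `residuals()`.

## Stage 2: diffusion on the latent grid

The diffusion model needs inputs near [-1, 1]. Because quantization keeps
the continuous latents close to the codebook, the minimum and maximum over
all codebook components approximate the latent range; `latent_normalizer()`
stores these two scalars and `latent_normalize()` applies the min-max map.
Sampled latents are clipped to [-1, 1] before the inverse map (configurable)
so that decoding never sees out-of-codebook values.

The forward process follows the standard DDPM formulation: a linear beta
schedule (`make_noise_schedule()`; defaults beta in [1e-4, 0.02], T = 1000
at full scale, T = 100 at desk scale — neither T nor the schedule is
prescribed by the method itself, so they are configuration defaults), the
closed-form marginal `q_sample()`, epsilon-prediction training
(`denoise_loss()`), and ancestral sampling (`p_sample_step()`,
`sample_latent()`) with `sigma^2 = beta_t` by default (`"posterior"`
available). No noise is injected at the final step.

The denoiser is a small two-level U-Net over the latent grid. Its
convolutions use 3 x 3 x 1 kernels and downsampling acts only on the
high-resolution plane (stride (2, 2, 1)), so shallow latent depths survive
several levels; upsampling is a transposed convolution and the level-1
features are concatenated back as a skip connection. At the coarse level
each block is followed by **spatial attention** (self-attention among
in-plane positions, treating depth as extra batch) and then **depth
attention** (self-attention across slices, treating the plane as batch),
each with a residual connection — the factorization that gives the model
through-plane consistency at tractable cost. The sinusoidal timestep
embedding is projected per block and added channel-wise after the first
convolution; where exactly the embedding enters is an open design choice
and this is ours. Attention only at the coarse level keeps desk-scale cost
low; the attention operators themselves (`spatial_attention()`,
`depth_attention()`) are exported and shape-generic.

`generate_volume()` (and the `simulate()` method) run the full path:
sample latent → clip → denormalize → quantize against the codebook →
decode.

## The phantom cohort generator

`phantom_spec()` / `generate_cohort()` define the synthetic study cohorts:
a large centered body ellipsoid (the organ analog, also the segmentation
ground truth), a configurable number of inner ellipsoids with random
centers, semi-axes (2-5 voxels by default) and intensities (0.5-1 against
a 0.25 body), a random degree-<=2 polynomial multiplicative bias field
bounded by 0.2 (the MR inhomogeneity analog), additive Gaussian noise
(sd 0.02), and a final min-max normalization to [-1, 1]. Cohort member i
uses seed `seed + i - 1`, so cohorts are reproducible and extendable.

These phantoms emulate the statistical structure the pipeline cares about
— smooth anatomy-like foreground of varying geometry and intensity on a
dark background, paired masks, field inhomogeneity, noise — but not the
texture, k-space artefacts or pathology of real MR/CT. Passing tests
therefore demonstrate that the machinery (compression, diffusion,
metrics, transfer) behaves as designed, not that the models reach clinical
image quality.

## Quality metrics

`ssim()`/`ms_ssim()` use 3D Gaussian windows (window 7, sigma 1.5,
data range 2 for [-1, 1] volumes): the volumes, not their slices, are the
objects of comparison. MS-SSIM pools by 2x averaging per scale, applies
the luminance term only at the coarsest scale, and automatically reduces
the scale count (renormalizing the standard 5-scale weights) when an axis
becomes smaller than the window — a depth-8 grid supports one scale, a
64^3 volume four. The statistics use zero-padded "same" filtering; the
symmetric window makes the filter self-adjoint, which keeps the analytic
MS-SSIM gradient (used when the metric serves as a training loss) exact;
all hand-derived gradients in the package are verified against finite
differences in the test suite.

`pairwise_diversity()` is the mode-collapse probe: the mean MS-SSIM over
seeded random pairs of distinct items. A generator that always emits the
same volume scores exactly 1; diverse cohorts score lower. The package
reproduces this as an ordering property (collapsed > generated samples >
training cohort), not as the absolute values reported for any particular
medical dataset, which depend on data we do not have.

`dice()` and `bootstrap_sd()` (standard deviation of 1000 resampled means)
quantify segmentation performance and its uncertainty.

## Self-supervised pretraining and scarce-label fine-tuning

The downstream experiment mirrors the institutional-transfer scenario:
synthetic volumes from one source pretrain a segmentation backbone that is
then fine-tuned on few labeled pairs from another.

* `mask_random_patches()` implements the inpainting pretext: axis-aligned
  patches (default 4 x 4 x 2, fill value 0 — the midpoint of [-1, 1]) are
  drawn until at least `mask_ratio` (default 0.3) of the volume is masked;
  random horizontal/vertical flips are applied identically to input, mask
  and target. The masked fraction is therefore bounded by
  `mask_ratio + patch_volume / total_volume`.
* `pretrain_inpainter()` trains a small 3-level encoder-decoder trunk with
  skip connection to reconstruct the original volume, with the
  0.5 L1 + 0.5 (1 - MS-SSIM) objective and AdamW (lr 1e-3, weight decay
  0.01, decoupled).
* `finetune_segmenter()` swaps a two-class head onto the (optionally
  pretrained) trunk and minimizes 0.5 cross-entropy + 0.5 (1 - soft Dice)
  with train-time augmentation: flips, small affine (zoom +-5%, shift
  +-2 voxels; nearest-neighbour for the mask), ghosting (periodic
  slice-intensity modulation — the simplest MR-ghosting analog), Gaussian
  noise, blur, bias field and gamma, applied in that order.
* `finetune_fractions()` fixes a held-out test split first, shuffles the
  training pool once per seed, and uses nested prefixes as label subsets
  (5% within 10% within 20% ...), so the fraction curves are comparable;
  it records mean test Dice and its bootstrap SD per fraction.

The equal 0.5/0.5 loss weights, the masking defaults, and "convergence"
recast as a fixed small step budget are desk-scale design choices; the
optimizer settings are as stated above.

## Numerical and design notes

* Index convention: 0-based (row, column, slice); "vertical" flips reverse
  the first axis.
* `center_crop()` keeps indices `floor((n-m)/2) .. floor((n-m)/2)+m-1` and
  pads oversize targets symmetrically with the volume minimum (the
  air/background analog; extra voxel on the high side), so cropping
  heterogeneous cohorts to a uniform shape always succeeds.
* Resampling and resizing are trilinear with endpoint-aligned sampling
  (corner voxels map to corner voxels), which preserves linear ramps
  exactly and makes identity targets exact; no antialiasing filter is
  applied. `split_bilateral()` drops the middle column for odd widths.
* Quantization ties break to the lowest codebook index; EMA counts are
  floored at 1e-5 when dividing. The geometric EMA convergence rate equals
  the decay exactly once the counts reach their stationary value (the
  per-step assignment count); during the transient the ratio differs.
* The reverse-step contraction toward x0 under a perfect noise oracle
  holds for the coefficients and on average over draws, not pointwise:
  individual draws where the signal and noise terms cancel inside x_t can
  move slightly away. Tests assert the average/majority form.
* Training loops abort with diagnostics on non-finite losses rather than
  continuing.
* Problem sizes used by the test-suite and the acceptance script — 16 x
  16 x 8 phantoms, cohorts of 8-60, 200 VQ-GAN steps, 250 diffusion steps
  at T = 100, 60 pretraining steps, fractions evaluated at 5% — are the
  package's desk-scale study conditions, chosen so every stage trains
  visibly (loss drops, ordered compression fidelity, diverse samples)
  within minutes on one CPU.

## Known limitations

* The neural-network engine is deliberately minimal (single-head
  attention, no mixed precision, one-sample microbatching); it is meant
  for method-level correctness and desk-scale experiments, not for
  training at clinical resolution.
* The perceptual reconstruction mode is a hook, not a shipped capability.
* Phantom realism is structural, not textural; absolute diversity or Dice
  values on phantoms do not transfer to any medical dataset.
* Accelerated samplers (e.g. DDIM), conditioning, and multi-class
  segmentation are out of scope.
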