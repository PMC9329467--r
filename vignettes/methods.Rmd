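---
title: "Sketch-conditioned CT synthesis: models, preprocessing and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-conditioned CT synthesis: models, preprocessing and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sketch2ct)
```

## The problem

Collecting large annotated sets of lung-tumor CT images is hard, which limits
deep-learning classifiers for tasks such as histological typing. One remedy is
to synthesize additional lesion images. `sketch2ct` implements a conditional
image-to-image route to that goal: a clinician (or an edge detector standing in
for one) provides a free-form sketch of a lesion, and a generative adversarial
translator renders a plausible lung-window CT patch with that shape. Because a
plain translator maps one sketch to exactly one image, the package also
provides a style-modulated variant that draws a random latent per image and so
yields *many* distinct CT renders per sketch — the property that makes
large-scale augmentation from a handful of sketches possible.

## Models

**Baseline translator (pix2pix-style).** The generator is a U-Net with seven
4x4 stride-2 down-convolutions (leaky-ReLU 0.2; instance normalisation except
at the first stage and the 1x1 bottleneck) and seven 4x4 stride-2 transposed
up-convolutions (ReLU, instance norm), each decoder stage skip-connected to the
encoder stage of equal resolution, ending in a tanh head. Channel widths run
64, 128, 256, 512, 512, 512, 512 at the default `base_channels = 64` (capped at
8x the base). The discriminator is a conditional patch classifier: sketch and
image are concatenated channelwise and reduced by four stride-2 convolutions to
a grid of sigmoid outputs. The training objective is the conditional
minimax value with an L1 reconstruction term,

$$ \min_G \max_D \; \mathbb{E}[\log D(x\mid y)] +
   \mathbb{E}[\log(1 - D(G(z\mid y)))] + \lambda\,\mathbb{E}\|x - G(z\mid y)\|_1 . $$

We use the non-saturating generator form ($-\log D(G)$) — universal GAN
practice — and $\lambda = 100$, the canonical translation-task choice.
Optimisation is Adam($\beta_1 = 0.9$, $\beta_2 = 0.999$) at learning rate
1e-5, batch 5, 400 epochs (defaults of `train_config()`).

**Style-modulated translator.** The decoder's seven up-convolutions are
replaced by style blocks: nearest x2 upsampling followed by a 3x3 convolution
whose kernel is rescaled per input channel by a style signal. A shared mapping
network (four fully connected layers, leaky-ReLU) turns a 512-dimensional
standard-normal latent into a style vector; each block owns a further
four-layer fully connected head that maps the style vector to its channel
scales (final bias initialised at 1 so the identity modulation is the starting
point). We enable StyleGAN2-style weight demodulation by default
(config-switchable): each modulated kernel is renormalised per output channel
by $1/\sqrt{\sum k'^2 + 10^{-8}}$, which prevents activation-magnitude
blow-up without data-dependent normalisation. The discriminator and losses are
unchanged; training length defaults to 200 epochs. Both a shared mapping
network and per-block heads are present: the two natural placements of the
four dense layers are not mutually exclusive, and implementing both is the
more general design (the per-block heads subsume the single-network
alternative).

The modulation/demodulation algebra is exposed directly as
`modulated_conv()`, and reduces exactly to a plain convolution for unit scales
with demodulation off.

**Autodiff engine.** No deep-learning framework is used: the package carries a
compact reverse-mode autodiff core (`R/autograd.R`) whose convolutions are
BLAS-backed im2col matrix products. Graph nodes are environments; node creation
order doubles as the topological order for the backward sweep. Ops accept raw
arrays or nodes, so inference passes build no graph. Every operator's analytic
gradient is checked against central finite differences in the test suite.

## Preprocessing

From an annotated volume the pipeline: (1) crops a cube of physical side twice
the tumor long diameter, padding outside voxels with air (-1000 HU); (2)
resamples trilinearly to 0.625 mm isotropic voxels; (3) extracts 2D slices —
for testing, the single central axial plane; for training, oblique planes
through the cube center at all 49 combinations of -30..30 degrees (10-degree
steps) of left-right and head-tail tilt, each also mirrored left-right, i.e.
98 images per tumor (so 127 training tumors yield 12446 images and 20 test
tumors yield 20); (4) windows HU with the lung window (level -600, width 1600)
to 8 bits, rounding half-up so the window center maps to 128; (5) resizes
bilinearly to 128x128; and (6) derives the paired sketch surrogate by Canny
edge detection with a 5x5 Gaussian (sigma 1.1), Sobel gradients, quantised
non-maximum suppression and hysteresis at thresholds 128/200. The 7x7 angle
grid plus mirroring is the unique enumeration consistent with both printed
dataset totals, and is adopted for that reason. Rotations compose about the
image axes through the cube center with nearest-border padding; the Canny
convolutions use exact (non-FFT) arithmetic because non-maximum suppression
breaks ties with strict inequalities and is sensitive to round-off on flat
regions.

Hand-drawn sketches are supported through `binarize_sketch()` (dark-on-light
scans; per-image threshold) and emulated by `make_hand_sketch()`, which keeps
the central lesion contour, keeps peripheral structures with a smoothly varying
probability equal to `detail_level`, and adds stroke-thickness jitter and
patchy erasures — a spectrum from lesion-only outlines to detailed tracings.

## Synthetic phantoms

The clinical dataset behind this method is private, so the package generates
its own study material: seeded phantom volumes on a 0.625 x 0.625 x 0.5 mm
grid containing a lobulated ellipsoidal tumor of specified long diameter
(soft-tissue HU around +30; the margin perturbation vanishes along the long
axis so the rendered diameter matches the annotation), curvilinear vessels,
a chest-wall band, optional Gaussian HU noise, and either a flat air-density
background (-850 HU) or a "pneumonia-like" one with raised attenuation and
patchy consolidation. Three surrogate histology classes differ in margin
lobulation, internal texture amplitude and rim sharpness (`ADC_like`,
`SCC_like`, `SCLC_like`), deliberately made strongly separable so the
augmentation harness has learnable signal. The phantoms are *not*
anatomically realistic — no airway tree, no fissures, no realistic vessel
topology, no scanner reconstruction effects — so passing tests demonstrate
pipeline correctness and directional learning behaviour, not clinical image
fidelity.

HU levels are fixed constants chosen so the lung window produces visible
contrast; with noise, vessels and chest wall disabled a phantom contains
exactly the background and tumor levels, which several tests exploit.

## Metrics

`mse`/`psnr`/`ssim` follow the printed definitions: PSNR is
$10\log_{10}(255^2/\mathrm{MSE})$ with identical images reported at a 99 dB
sentinel so aggregates stay finite; SSIM is the *global-statistics* form (the
printed equation carries no window) with constants $C_1 = 0.01\cdot255^2$,
$C_2 = 0.03\cdot255^2$ taken verbatim, population variances, and an optional
sliding-window mode behind a flag. FID fits Gaussians to feature groups and
evaluates $\|\mu_F-\mu_G\|^2 + \mathrm{Tr}(\Sigma_F+\Sigma_G -
2(\Sigma_F\Sigma_G)^{1/2})$, computing the square root on the symmetrised
product with eigenvalues below $-10^{-8}$ clipped. LPIPS channel-unit-
normalises each stage's feature maps, takes channel-weighted squared
differences (uniform weights by default), averages per map and sums over
stages; a `normalize = FALSE` flag exposes the raw-difference arithmetic.
`evaluate_images()` follows the reporting semantics of the method: pairwise
metrics are averaged per image pair, FID is computed once between groups.

The feature backbone is pluggable. The default is a fixed-seed randomly
initialised small CNN — a recognised lightweight stand-in for pretrained
perceptual backbones and the only fully self-contained choice; pretrained
weights can be supplied through the same `layers` interface. Absolute
FID/LPIPS values under this backbone are therefore not comparable to values
computed with Inception-v3/AlexNet features.

## Augmentation harness

`generate_augmented_set()` generates per class `n_edges x n_per_edge` images
(the one-to-one baseline deduplicates to one per edge, with a warning).
`pretrain_then_finetune()` trains all classifier layers on generated images
with SGD, then freezes the convolutional stack and updates only the fully
connected layers on real images. `cross_validate()` runs three repeats of
threefold cross-validation, stratified by class at the tumor level so no
slice of a held-out tumor can appear among its fold's training inputs, and
reports fold accuracies (test and memorisation-check train values). The
no-pretraining baseline trains all layers on real images only: the spec'd
zero-pretraining limit of `pretrain_then_finetune()` would leave random
frozen convolutions and understate the baseline, so the comparison uses the
stronger form.

## Desk-scale problem sizes

The published training scale (12446 images, 400 epochs at 128x128 with
64-channel stems) is far beyond a laptop-class CPU run; the package's tests
and `scripts/acceptance.R` therefore exercise identical code paths at reduced
width and resolution, chosen once as follows:

* combinatorial checks (slice and generation counts) run at full 128x128
  resolution with `base_channels = 2`, since counts are width-independent;
* learning checks (L1 descent, augmentation benefit) run at 32x32 with
  `base_channels = 16`, learning rate 2e-4 (the classic translation-GAN
  rate; at 1e-5 a 20-step smoke run moves weights by ~1e-4 and the descent
  signal would drown in shuffling noise), 8 training epochs;
* the augmentation study uses 36 classification tumors (12 per class), 18
  edge-source tumors contributing 30 edges per class, 5 latents per edge
  (450 generated images), and SGD at 5e-3 for 20 pretraining / 30
  fine-tuning epochs;
* phantom diameters are drawn from 14-30 mm by default and 14-24 mm in the
  heavier tests.

The published-protocol hyperparameters remain the exported defaults
(`train_config()`, `classifier_config()`, `generator_config()`).

## Numerical choices and edge cases

* Half-up rounding when quantising windowed HU (the window center must map
  deterministically to 128; base `round()` is banker's rounding).
* Crop padding uses -1000 HU (air), the physically neutral filler.
* Score clamping at 1e-7 keeps the adversarial logs finite; a non-finite
  loss aborts training with a diagnostic rather than continuing silently.
* Infinite PSNR on identical images is reported as a 99 dB sentinel.
* Tumor masks are rendered before noise, so annotation checks are exact.
* All randomness flows through an isolated RNG helper: a single integer seed
  reproduces phantoms, shuffles, latents and fold splits bit-identically,
  and never perturbs the caller's RNG stream.

A caveat on the augmentation comparison: the phantom classes are strongly
separable by design, so the real-only baseline already scores high at this
scale, and the margin between the augmented and baseline arms is small
relative to fold-to-fold variability. The directional benefit holds under the
documented study conditions but should not be read as a general effect-size
estimate; on other random draws of the phantom cohort the two arms can come
out within noise of each other (the acceptance script reports whichever way
its own draw lands).

## Known limitations

Phantom realism is deliberately minimal (see above). The style heads emit
per-input-channel scales only — no per-layer noise injection, style mixing or
truncation. The discriminator layout below 128x128 collapses to a 1x1 patch
grid, i.e. an image-level discriminator, at 32x32. SSIM's global form can
mask local structural differences; the windowed variant is available but not
the default. FID under the small random backbone is only meaningful for
comparisons that share the backbone. The oblique-slice enumeration and the
axes the tilts compose about admit several readings; the implemented choice
(full 7x7 tilt grid about the image axes, plus mirroring) is the unique one
consistent with the dataset totals the pipeline is required to reproduce.
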