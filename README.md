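# sketch2ct

Sketch-conditioned synthesis of lung-tumor CT images for data augmentation,
in pure R.

Clinicians can convey the shape of a lesion with a free-form sketch far more
easily than they can share patient images. `sketch2ct` turns such sketches
(or Canny edge maps standing in for them) into lung-window CT patches with a
conditional GAN translator, and evaluates whether the synthesized images help
a downstream histology classifier. Two models are provided:

* **pix2pix-style baseline** — a seven-level U-Net generator with a
  conditional PatchGAN discriminator, trained on the objective
  `min_G max_D E[log D(x|y)] + E[log(1 - D(G(z|y)))] + lambda E||x - G(z|y)||_1`
  (non-saturating generator form, `lambda = 100`). One sketch maps to one
  image.
* **style-modulated variant** — the seven decoder up-convolutions become
  style blocks: a mapping network turns a 512-dimensional standard-normal
  latent into a style vector, per-block dense heads emit per-channel kernel
  scales, and StyleGAN2-style weight demodulation keeps activations bounded.
  One sketch plus fresh latents yields arbitrarily many distinct images —
  the property that makes sketch-based augmentation scale.

Around the models the package implements the full experimental pipeline:

* **phantoms** — seeded synthetic lung-CT volumes (lobulated tumor, vessels,
  chest wall, healthy or pneumonia-like background, three separable texture
  classes) standing in for the private clinical data, plus hand-sketch
  emulation;
* **preprocess** — VOI cropping (cube side = 2 x tumor long diameter),
  0.625 mm isotropic trilinear resampling, oblique-slice augmentation
  (7 x 7 tilt grid x mirroring = 98 slices/tumor), lung windowing
  (-600/1600), bilinear resize to 128 x 128, Canny sketch surrogates
  (5 x 5 Gaussian, hysteresis 128/200), PNG + manifest I/O;
* **metrics** — PSNR, global-statistics SSIM (C1 = 0.01*255^2,
  C2 = 0.03*255^2), group FID with a symmetrised matrix square root, and
  LPIPS over channel-normalised feature maps of a pluggable backbone;
* **augeval** — class-wise batch generation, classifier pretraining on
  generated images with FC-only fine-tuning on real ones, and repeated
  stratified (tumor-level) cross-validation.

There is no deep-learning framework underneath: the package ships a compact
reverse-mode autodiff engine with BLAS-backed im2col convolutions, and every
operator's gradient is verified against finite differences in the tests.

## Worked example

```r
library(sketch2ct)

# 1. a small labeled phantom dataset and its (sketch, CT) pairs at 32 px
ds <- make_paired_dataset(18, spec_ranges = list(diameter_mm = c(14, 24)), seed = 200)
pairs <- list()
for (d in ds) {
  voi <- resample_isotropic(crop_voi(d$volume))
  pairs <- c(pairs, voi_to_pairs(voi, train_mode = TRUE, size = 32L)[seq(1, 98, by = 20)])
}

# 2. train the style-modulated translator briefly
cfg <- generator_config(image_size = 32, depth = 5, base_channels = 16,
                        use_style = TRUE, latent_dim = 64)
run <- train_pix2pix(pairs, build_style_generator(cfg, seed = 1),
                     build_discriminator(cfg, seed = 2),
                     train_config(learning_rate = 2e-4, epochs = 8, batch_size = 5, seed = 1))
round(run$history$g_l1, 4)
#> [1] 0.2296 0.1357 0.1029 0.0868 0.0773 0.0708 0.0661 0.0623

# 3. one sketch, five distinct images
imgs <- generate_images(run$generator, pairs[[1]]$sketch / 255, n = 5, seed = 7)
length(unique(lapply(imgs, function(m) m[1:4, 1:4])))
#> [1] 5
```

The generator L1 term falls monotonically (0.23 to 0.06 in eight epochs) and
the style model returns five pairwise-distinct renders of the same sketch —
the one-to-many behaviour the baseline cannot produce (its five outputs would
be identical).

A thin CLI over the same functions is installed at `inst/exec/sketch2ct`
(subcommands `phantoms`, `preprocess`, `train`, `metrics`, `summary`).

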