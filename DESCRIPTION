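Package: sketch2ct
Title: Sketch-Conditioned Lung Tumor CT Synthesis with Style-Modulated Pix2pix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional image-to-image translation toolkit for generating
    lung-window CT tumor images from free-form sketches or Canny edge maps.
    Implements a pix2pix U-Net generator/PatchGAN discriminator pair and a
    style-modulated variant (mapping network plus style blocks with weight
    demodulation) enabling one-to-many generation, on top of a compact
    reverse-mode autodiff engine with BLAS-backed im2col convolutions.
    Includes the full CT preprocessing pipeline (VOI cropping, isotropic and
    oblique trilinear resampling, lung windowing, Canny sketch surrogates),
    seeded synthetic lung phantom generation, PSNR/SSIM/FID/LPIPS evaluation,
    and a data-augmentation harness with repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
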