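test_that("generator preserves spatial shape across sizes and configs", {
  for (sz in c(32L, 64L)) {
    g <- build_generator(fx_cfg(sz, base = 4L), seed = 1)
    out <- generator_forward(g, matrix(runif(sz * sz), sz, sz))
    expect_equal(dim(out), c(sz, sz, 1L, 1L))
    expect_true(all(out >= -1 & out <= 1))
  }
  expect_error(generator_config(image_size = 96, depth = 7), "divisible")
})

test_that("batch members do not leak into each other", {
  sz <- 32L
  g <- build_generator(fx_cfg(sz), seed = 2)
  a <- matrix(runif(sz * sz), sz, sz); b <- matrix(runif(sz * sz), sz, sz)
  two <- array(c(a, b), c(sz, sz, 1L, 2L))
  two0 <- array(c(a, 0 * b), c(sz, sz, 1L, 2L))
  o1 <- generator_forward(g, two)
  o2 <- generator_forward(g, two0)
  expect_equal(o1[, , , 1L], o2[, , , 1L])
  expect_gt(max(abs(o1[, , , 2L] - o2[, , , 2L])), 0)
})

test_that("style generator is one-to-many and latent-deterministic", {
  sz <- 32L
  gs <- build_style_generator(fx_cfg(sz, style = TRUE), seed = 3)
  sk <- fx_pairs(sz)[[1]]$sketch / 255
  z <- sample_latent(2, 32L, seed = 5)
  skb <- array(rep(sk, 2), c(sz, sz, 1L, 2L))
  out <- generator_forward(gs, skb, latent = z)
  expect_gt(max(abs(out[, , , 1L] - out[, , , 2L])), 0)
  rep1 <- generator_forward(gs, sk, latent = z[, 1])
  rep2 <- generator_forward(gs, sk, latent = z[, 1])
  expect_identical(rep1, rep2)
  g0 <- build_generator(fx_cfg(sz), seed = 3)
  expect_equal(dim(out[, , , 1L, drop = FALSE]), dim(generator_forward(g0, sk)))
  expect_error(generator_forward(gs, sk, latent = rnorm(5)), "latent")
  expect_error(generator_forward(gs, sk), "latent")
})

test_that("per-pixel latent variance separates style from baseline generation", {
  sz <- 32L
  gs <- build_style_generator(fx_cfg(sz, style = TRUE), seed = 4)
  sk <- fx_pairs(sz)[[2]]$sketch / 255
  imgs <- generate_images(gs, sk, n = 10L, seed = 11)
  stack <- simplify2array(imgs)
  expect_gt(mean(apply(stack, c(1, 2), stats::sd)), 0)
  g0 <- build_generator(fx_cfg(sz), seed = 4)
  imgs0 <- generate_images(g0, sk, n = 5L)
  stack0 <- simplify2array(imgs0)
  expect_identical(max(apply(stack0, c(1, 2), stats::sd)), 0)
  # seeded reproducibility of the whole set
  expect_identical(imgs, generate_images(gs, sk, n = 10L, seed = 11))
  expect_error(generate_images(gs, sk, n = 0L), "n must")
})

test_that("mapping network is deterministic, finite and length-checked", {
  gs <- build_style_generator(fx_cfg(32L, style = TRUE), seed = 6)
  z <- rnorm(32)
  w1 <- map_latent(z, gs)
  expect_identical(w1, map_latent(z, gs))
  expect_true(all(is.finite(map_latent(numeric(32), gs))))
  z2 <- rnorm(32)
  expect_false(identical(w1, map_latent(z2, gs)))
  expect_error(map_latent(rnorm(7), gs), "length")
  g0 <- build_generator(fx_cfg(32L), seed = 6)
  expect_error(map_latent(z, g0), "mapping")
})

test_that("modulated convolution reduces to plain convolution and scales linearly", {
  set.seed(21)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3, 1))
  k <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  plain <- get("ag_conv2d", envir = asNamespace("sketch2ct"))(x, k, NULL, stride = 1L, pad = 1L)
  expect_equal(modulated_conv(x, k, rep(1, 3), demodulate = FALSE), plain, tolerance = 1e-12)
  expect_equal(modulated_conv(x, k, rep(2.5, 3), demodulate = FALSE), 2.5 * plain,
               tolerance = 1e-12)
  # 1x1 toy: single in/out channel, central tap 2, style 3, input 5 -> 30
  k1 <- array(0, c(3, 3, 1, 1)); k1[2, 2, 1, 1] <- 2
  x1 <- array(5, c(1, 1, 1, 1))
  expect_equal(as.vector(modulated_conv(x1, k1, 3, demodulate = FALSE)), 30)
  expect_error(modulated_conv(x, k, rep(1, 4)), "length")
})

test_that("style generator has more parameters than the baseline", {
  cfg <- generator_config(image_size = 32, depth = 5, base_channels = 8,
                          latent_dim = 256L)
  cfg_s <- cfg; cfg_s$use_style <- TRUE
  expect_gt(model_parameter_count(build_style_generator(cfg_s, seed = 1)),
            model_parameter_count(build_generator(cfg, seed = 1)))
})

test_that("discriminator emits conditioned patch probabilities", {
  sz <- 32L
  d <- build_discriminator(fx_cfg(sz), seed = 7)
  sk <- fx_pairs(sz)[[1]]$sketch / 255
  im <- (fx_pairs(sz)[[1]]$ct / 127.5) - 1
  p <- discriminator_forward(d, sk, im)
  expect_true(all(p > 0 & p < 1))
  # swapped batch order permutes outputs
  sk2 <- fx_pairs(sz)[[2]]$sketch / 255
  im2 <- (fx_pairs(sz)[[2]]$ct / 127.5) - 1
  b12 <- discriminator_forward(d, array(c(sk, sk2), c(sz, sz, 1, 2)),
                               array(c(im, im2), c(sz, sz, 1, 2)))
  b21 <- discriminator_forward(d, array(c(sk2, sk), c(sz, sz, 1, 2)),
                               array(c(im2, im), c(sz, sz, 1, 2)))
  expect_equal(b12[, , , 1L], b21[, , , 2L])
  # conditioning is live: changing only the sketch changes the score
  expect_gt(max(abs(discriminator_forward(d, sk2, im) - p)), 0)
  expect_error(discriminator_forward(d, sk, matrix(0, 16, 16)), "mismatch")
})

test_that("bundle save/load round-trips weights and behaviour", {
  gs <- build_style_generator(fx_cfg(32L, style = TRUE), seed = 8)
  sk <- fx_pairs(32L)[[1]]$sketch / 255
  z <- sample_latent(1, 32L, seed = 2)
  before <- generator_forward(gs, sk, latent = z)
  path <- file.path(tempdir(), "bundle.rds")
  save_bundle(list(generator = gs, note = "ckpt"), path)
  back <- load_bundle(path)
  expect_equal(back$note, "ckpt")
  expect_equal(generator_forward(back$generator, sk, latent = z), before)
})
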