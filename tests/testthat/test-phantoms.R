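test_that("phantoms are bit-reproducible under a fixed seed", {
  sp <- phantom_spec(tumor_long_diameter_mm = 16, seed = 1)
  expect_identical(make_phantom(sp)$voxels, make_phantom(sp)$voxels)
  sp2 <- phantom_spec(tumor_long_diameter_mm = 16, seed = 2)
  expect_false(identical(make_phantom(sp)$voxels, make_phantom(sp2)$voxels))
})

test_that("degenerate composition yields exactly background and tumor levels", {
  sp <- phantom_spec(tumor_long_diameter_mm = 14, n_vessels = 0, chest_wall = FALSE,
                     noise_sd = 0, texture_amp = 0, rim_sharpness = 1, seed = 3)
  v <- make_phantom(sp)
  lv <- sort(unique(as.vector(v$voxels)))
  expect_length(lv, 2L)
  expect_gt(sum(v$tumor_mask), 0)
  expect_true(all(v$voxels[v$tumor_mask] == max(lv)))
  expect_true(all(v$voxels[!v$tumor_mask] == min(lv)))
})

test_that("rendered long diameter tracks the annotation within 10%", {
  for (d in c(14, 20, 28)) {
    v <- make_phantom(phantom_spec(tumor_long_diameter_mm = d, seed = 5),
                      spacing_mm = rep(0.625, 3))
    expect_lt(abs(measure_tumor_long_diameter(v) - d) / d, 0.10)
  }
})

test_that("tumor voxel count is positive and monotone in diameter", {
  counts <- vapply(c(12, 16, 20, 24), function(d)
    sum(make_phantom(phantom_spec(tumor_long_diameter_mm = d, seed = 4),
                     spacing_mm = rep(0.625, 3))$tumor_mask), numeric(1))
  expect_true(all(counts > 0))
  expect_true(all(diff(counts) >= 0))
})

test_that("pneumonia-like background raises lung-region mean HU at fixed seed", {
  mk <- function(style) make_phantom(phantom_spec(
    tumor_long_diameter_mm = 16, background_style = style, seed = 7,
    n_vessels = 0, chest_wall = FALSE, noise_sd = 0))
  vh <- mk("healthy"); vp <- mk("pneumonia_like")
  expect_identical(vh$tumor_mask, vp$tumor_mask)
  expect_gt(mean(vp$voxels[!vp$tumor_mask]), mean(vh$voxels[!vh$tumor_mask]))
})

test_that("spec validation rejects invalid parameters", {
  expect_error(phantom_spec(tumor_long_diameter_mm = 0), "positive")
  expect_error(phantom_spec(tumor_long_diameter_mm = -3), "positive")
  expect_error(phantom_spec(tumor_lobulation = 1.5), "lobulation")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
})

test_that("hand-sketch emulation honours its limits and determinism", {
  sk <- fx_pairs(32L)[[2]]$sketch
  expect_identical(make_hand_sketch(sk, detail_level = 1, jitter = 0), sk * 1L)
  low <- make_hand_sketch(sk, detail_level = 0, seed = 1)
  n <- dim(sk)
  cx <- (n[1] + 1) / 2; cy <- (n[2] + 1) / 2
  R <- outer(seq_len(n[1]) - cx, seq_len(n[2]) - cy, function(i, j) sqrt(i^2 + j^2))
  # at detail 0 with jitter, survivors stay in/near the central lesion zone
  expect_true(all(R[make_hand_sketch(sk, 0, seed = 1, jitter = 0) > 0] <= 0.36 * n[1]))
  expect_true(all(low %in% c(0L, 255L)))
  expect_identical(low, make_hand_sketch(sk, detail_level = 0, seed = 1))
  expect_false(identical(low, make_hand_sketch(sk, detail_level = 0, seed = 2)))
  expect_error(make_hand_sketch(matrix(0.5, 4, 4), 1), "binary")
})

test_that("paired dataset cycles classes, is seeded, and validates n", {
  ds <- fx_dataset()
  expect_length(ds, 6L)
  expect_equal(vapply(ds, `[[`, "", "class"),
               rep(c("ADC_like", "SCC_like", "SCLC_like"), 2))
  ds3 <- make_paired_dataset(3, spec_ranges = list(diameter_mm = c(14, 16)), seed = 9)
  expect_setequal(vapply(ds3, `[[`, "", "class"),
                  c("ADC_like", "SCC_like", "SCLC_like"))
  ds3b <- make_paired_dataset(3, spec_ranges = list(diameter_mm = c(14, 16)), seed = 9)
  expect_identical(lapply(ds3, function(d) d$volume$voxels),
                   lapply(ds3b, function(d) d$volume$voxels))
  expect_error(make_paired_dataset(0), ">= 1")
})

test_that("NIfTI + JSON sidecar round trip preserves volume and annotation", {
  v <- fx_dataset()[[1]]$volume
  stem <- file.path(tempdir(), "phantom_rt")
  write_phantom(v, stem, class_label = "ADC_like")
  r <- read_phantom(stem)
  expect_equal(dim(r$voxels), dim(v$voxels))
  expect_equal(r$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(r$tumor_center_voxel, v$tumor_center_voxel)
  expect_equal(r$tumor_long_diameter_mm, v$tumor_long_diameter_mm)
  expect_equal(attr(r, "class_label"), "ADC_like")
})
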