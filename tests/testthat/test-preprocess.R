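mk_vol <- function(dims = c(80, 80, 100), spacing = c(0.625, 0.625, 0.5),
                   center = NULL, d = 20, fill = NULL) {
  vox <- if (is.null(fill)) array(seq_len(prod(dims)), dims) else array(fill, dims)
  structure(list(voxels = vox, spacing_mm = spacing,
                 tumor_center_voxel = center %||% (dims + 1L) %/% 2L,
                 tumor_long_diameter_mm = d),
            class = "annotated_volume")
}

test_that("crop_voi produces a 2x-diameter cube and pads with air", {
  v <- mk_vol()
  voi <- crop_voi(v)
  expect_equal(dim(voi$voxels), c(64L, 64L, 80L))   # 2*20/spacing per axis
  ctr <- v$tumor_center_voxel
  expect_equal(voi$voxels[33, 33, 41],
               v$voxels[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
  corner <- crop_voi(mk_vol(center = c(1L, 1L, 1L)))
  expect_equal(dim(corner$voxels), c(64L, 64L, 80L))
  expect_true(any(corner$voxels == -1000))
  expect_error(crop_voi(mk_vol(d = 0)), "positive")
  bad <- mk_vol(); bad$tumor_center_voxel <- NULL
  expect_error(crop_voi(bad), "annotation")
})

test_that("isotropic resampling preserves extent, identity and constants", {
  voi <- crop_voi(mk_vol())
  iso <- resample_isotropic(voi)
  expect_equal(dim(iso$voxels), rep(64L, 3))
  expect_equal(iso$spacing_mm, 0.625)
  already <- structure(list(voxels = array(rnorm(8^3), rep(8, 3)),
                            spacing_mm = rep(0.625, 3),
                            tumor_long_diameter_mm = 2.5),
                       class = "voi_volume")
  expect_identical(resample_isotropic(already)$voxels, already$voxels)
  const <- crop_voi(mk_vol(fill = 7))
  expect_true(all(resample_isotropic(const)$voxels == 7))
  expect_error(resample_isotropic(voi, target_mm = 0), "positive")
})

test_that("slice extraction yields 1 test and 98 train images per VOI", {
  iso <- resample_isotropic(crop_voi(mk_vol(fill = 3)))
  expect_length(extract_slices(iso, train_mode = FALSE), 1L)
  tr <- extract_slices(iso, train_mode = TRUE)
  expect_length(tr, 98L)
  # 49 angle pairs, each with an unmirrored and a mirrored copy
  meta <- t(vapply(tr, function(s)
    c(attr(s, "angle_lr"), attr(s, "angle_ht"), attr(s, "mirrored")), numeric(3)))
  expect_equal(nrow(unique(meta[, 1:2])), 49L)
  expect_equal(sum(meta[, 3]), 49L)
  # constant cube -> constant slices at every obliquity
  expect_true(all(vapply(tr, function(s) all(s == 3), logical(1))))
  # mirrored copy is the column-reversed unmirrored slice
  expect_identical(unclass(tr[[2]])[, 64:1], unclass(tr[[1]])[, ])
  noncube <- crop_voi(mk_vol())
  expect_error(extract_slices(noncube, TRUE), "cubic")
})

test_that("lung windowing maps, clips, rounds half-up and is monotone", {
  expect_equal(apply_window(matrix(c(-1400, 200, -600, -2000, 500), 1)),
               matrix(c(0, 255, 128, 0, 255), 1))
  hu <- matrix(seq(-1600, 400, length.out = 64), 8, 8)
  w <- apply_window(hu)
  expect_true(all(diff(as.vector(w)) >= 0))
  expect_equal(range(w), c(0, 255))
  expect_true(all(apply_window(matrix(-2000, 4, 4)) == 0))
  expect_error(window_spec(width = 0), "positive")
})

test_that("model resize is bilinear, identity at target size, range-preserving", {
  img <- matrix(5, 64, 64)
  expect_true(all(resize_to_model(img) == 5))
  expect_equal(dim(resize_to_model(img)), c(128L, 128L))
  id <- matrix(rnorm(128^2), 128, 128)
  expect_identical(resize_to_model(id), id)
  checker <- outer(1:256, 1:256, function(i, j) ((i + j) %% 2) * 255)
  rs <- resize_to_model(checker)
  expect_true(all(rs >= 0 & rs <= 255))
  expect_error(resize_to_model(matrix(0, 10, 20)), "square")
})

test_that("sketch binarization follows the dark-on-light convention", {
  scan <- matrix(230, 16, 16); scan[5:8, 5:8] <- 40
  out <- binarize_sketch(scan, 128)
  expect_true(all(out[5:8, 5:8] == 255))
  expect_true(all(out[scan == 230] == 0))
  expect_true(all(binarize_sketch(scan, 0) == 0))
  expect_error(binarize_sketch(scan, 256), "threshold")
  expect_error(binarize_sketch(scan, -1), "threshold")
})

test_that("PNG round trips are lossless for CT renders and sketches", {
  p <- fx_pairs(32L)[[1]]
  dir <- file.path(tempdir(), "pairs_rt")
  unlink(dir, recursive = TRUE)
  manifest <- write_pairs(list(p), dir, voi_id = "v1", class_label = "ADC_like")
  expect_equal(nrow(manifest), 1L)
  expect_true(all(c("ct_path", "sketch_path", "voi_id", "angle_lr", "angle_ht",
                    "mirrored", "class") %in% names(manifest)))
  expect_equal(read_image_8bit(manifest$ct_path[1]), unname(p$ct))
  expect_equal(read_image_8bit(manifest$sketch_path[1]), matrix(as.numeric(p$sketch), 32, 32))
  # RGB CT file carries three identical channels
  rgb <- png::readPNG(manifest$ct_path[1])
  expect_equal(rgb[, , 1], rgb[, , 2])
  expect_equal(rgb[, , 1], rgb[, , 3])
})

test_that("slice-count arithmetic scales as 98 per training VOI", {
  ds <- fx_dataset()[1:2]
  n_train <- sum(vapply(ds, function(d)
    length(extract_slices(resample_isotropic(crop_voi(d$volume)), TRUE)), numeric(1)))
  n_test <- sum(vapply(ds, function(d)
    length(extract_slices(resample_isotropic(crop_voi(d$volume)), FALSE)), numeric(1)))
  expect_equal(n_train, 98 * 2)
  expect_equal(n_test, 2)
})
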