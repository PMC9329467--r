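#' Lung window specification
#'
#' Linear HU-to-display mapping parameterised by center (`level`) and
#' `width`; the defaults are the lung window used throughout (level -600,
#' width 1600, i.e. HU -1400..200 to 0..255).
#'
#' @param level Window center in HU.
#' @param width Window width in HU (> 0).
#' @return List of class `window_spec`.
#' @export
window_spec <- function(level = -600, width = 1600) {
  if (width <= 0) stop("window width must be positive")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Crop the volume of interest around the tumor
#'
#' Extracts a cube centered on the annotated tumor center whose physical
#' side is twice the tumor long diameter (context for surrounding
#' structures); voxels falling outside the scanned volume are padded with
#' air (-1000 HU).
#'
#' @param volume An `annotated_volume`.
#' @return A `voi_volume`: list with `voxels`, `spacing_mm`,
#'   `tumor_long_diameter_mm`.
#' @export
crop_voi <- function(volume) {
  if (is.null(volume$tumor_center_voxel) || is.null(volume$tumor_long_diameter_mm))
    stop("volume lacks a tumor annotation")
  d <- volume$tumor_long_diameter_mm
  if (!is.finite(d) || d <= 0) stop("tumor long diameter must be positive")
  sp <- volume$spacing_mm
  n <- as.integer(round(2 * d / sp))
  ctr <- volume$tumor_center_voxel
  dims <- dim(volume$voxels)
  out <- array(-1000, n)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    idx <- ctr[ax] - n[ax] %/% 2L + seq_len(n[ax])
    ok <- idx >= 1L & idx <= dims[ax]
    src[[ax]] <- idx[ok]
    dst[[ax]] <- which(ok)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    volume$voxels[src[[1]], src[[2]], src[[3]]]
  structure(list(voxels = out, spacing_mm = sp, tumor_long_diameter_mm = d),
            class = "voi_volume")
}

#' Resample a VOI to isotropic voxels
#'
#' Trilinear resampling to `target_mm` isotropic spacing (default 0.625 mm,
#' the in-plane pixel size of the source scans); the physical extent is
#' preserved to within one voxel. A volume already at the target spacing is
#' returned unchanged.
#'
#' @param voi A `voi_volume`.
#' @param target_mm Target isotropic spacing (> 0).
#' @return A `voi_volume` with scalar `spacing_mm = target_mm`.
#' @export
resample_isotropic <- function(voi, target_mm = 0.625) {
  if (target_mm <= 0) stop("target spacing must be positive")
  sp <- voi$spacing_mm
  if (length(sp) == 1L) sp <- rep(sp, 3)
  if (is.null(sp)) stop("spacing metadata missing")
  dims <- dim(voi$voxels)
  if (all(abs(sp - target_mm) < 1e-12)) {
    voi$spacing_mm <- target_mm
    return(voi)
  }
  # a VOI cube has physical side 2 x long diameter on every axis; derive the
  # common output side from that so per-axis rounding cannot break cubicity
  nd <- if (!is.null(voi$tumor_long_diameter_mm)) {
    rep(max(as.integer(round(2 * voi$tumor_long_diameter_mm / target_mm)), 1L), 3L)
  } else {
    pmax(as.integer(round(dims * sp / target_mm)), 1L)
  }
  # voxel-center alignment: output center i maps to input index
  # (i - 0.5) * target/spacing + 0.5
  xi <- (seq_len(nd[1]) - 0.5) * target_mm / sp[1] + 0.5
  yi <- (seq_len(nd[2]) - 0.5) * target_mm / sp[2] + 0.5
  zi <- (seq_len(nd[3]) - 0.5) * target_mm / sp[3] + 0.5
  co <- expand.grid(x = xi, y = yi, z = zi)
  vox <- array(interp_trilinear(voi$voxels, co$x, co$y, co$z), nd)
  structure(list(voxels = vox, spacing_mm = target_mm,
                 tumor_long_diameter_mm = voi$tumor_long_diameter_mm),
            class = "voi_volume")
}

slice_angles <- function() seq(-30L, 30L, by = 10L)

rot_y <- function(th) matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
rot_x <- function(th) matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)

#' Extract 2D slices from a VOI
#'
#' In test mode returns the single central axial plane (the representative
#' image of the tumor). In train mode returns 98 images: oblique planes
#' through the cube center at every pair of tilts (-30..30 degrees in 10
#' degree steps) about the left-right and head-tail axes (7 x 7 = 49
#' orientations), each emitted unmirrored and left-right mirrored. Oblique
#' planes are resampled by trilinear interpolation with nearest-border
#' padding.
#'
#' @param voi An isotropic, cubic `voi_volume`.
#' @param train_mode Logical; see above.
#' @return List of HU matrices with attributes `angle_lr`, `angle_ht`,
#'   `mirrored`.
#' @export
extract_slices <- function(voi, train_mode = FALSE) {
  dims <- dim(voi$voxels)
  if (length(unique(dims)) != 1L || length(voi$spacing_mm) != 1L)
    stop("extract_slices requires a cubic, isotropic VOI")
  n <- dims[1]
  if (!train_mode) {
    sl <- voi$voxels[, , n %/% 2L + 1L]
    attr(sl, "angle_lr") <- 0L; attr(sl, "angle_ht") <- 0L; attr(sl, "mirrored") <- FALSE
    return(list(sl))
  }
  ctr <- (n + 1) / 2
  base <- seq_len(n) - ctr
  gi <- rep(base, times = n); gj <- rep(base, each = n)
  out <- vector("list", 2L * 49L)
  k <- 1L
  for (a_lr in slice_angles()) {
    for (a_ht in slice_angles()) {
      R <- rot_y(a_lr * pi / 180) %*% rot_x(a_ht * pi / 180)
      u <- R %*% c(1, 0, 0); v <- R %*% c(0, 1, 0)
      px <- ctr + gi * u[1] + gj * v[1]
      py <- ctr + gi * u[2] + gj * v[2]
      pz <- ctr + gi * u[3] + gj * v[3]
      sl <- matrix(interp_trilinear(voi$voxels, px, py, pz), n, n)
      for (mir in c(FALSE, TRUE)) {
        s <- if (mir) sl[, rev(seq_len(n))] else sl
        attr(s, "angle_lr") <- a_lr; attr(s, "angle_ht") <- a_ht
        attr(s, "mirrored") <- mir
        out[[k]] <- s; k <- k + 1L
      }
    }
  }
  out
}

#' Apply an intensity window
#'
#' Linear map of `[level - width/2, level + width/2]` HU to `[0, 255]`,
#' clipped outside and quantised with half-up rounding (so the window
#' center maps to 128).
#'
#' @param hu_image Numeric matrix of HU values.
#' @param spec A [window_spec()].
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
apply_window <- function(hu_image, spec = window_spec()) {
  if (!inherits(spec, "window_spec")) stop("spec must be a window_spec")
  lo <- spec$level - spec$width / 2
  v <- (hu_image - lo) / spec$width * 255
  round_half_up(pmin(pmax(v, 0), 255))
}

#' Resize a square image for the models
#'
#' Bilinear resize to `size` x `size` (default 128); inputs already at the
#' target size are returned unchanged.
#'
#' @param image Square numeric matrix.
#' @param size Target side length.
#' @return `size` x `size` matrix.
#' @export
resize_to_model <- function(image, size = 128L) {
  d <- dim(image)
  if (d[1] != d[2]) stop("input image must be square")
  if (d[1] == size) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = size, h = size,
                         filter = "bilinear")
  matrix(EBImage::imageData(out), size, size)
}

#' Binarize a scanned sketch
#'
#' Dark-on-light scan convention: pixels darker than `threshold` become
#' strokes (255), everything else background (0). In practice the threshold
#' is tuned per scan with visual feedback.
#'
#' @param scanned_image Grayscale matrix in `[0, 255]`.
#' @param threshold Integer in `[0, 255]`.
#' @return Binary matrix with values in `{0, 255}`.
#' @export
binarize_sketch <- function(scanned_image, threshold) {
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  (scanned_image < threshold) * 255L
}

#' Run the full slice pipeline on one VOI
#'
#' Windows each extracted slice, resizes to the model resolution, and
#' derives the paired edge image with [canny_edges()].
#'
#' @param voi An isotropic cubic `voi_volume`.
#' @param train_mode Passed to [extract_slices()].
#' @param window A [window_spec()].
#' @param canny A [canny_spec()].
#' @param size Model image side (default 128).
#' @return List of `slice_pair` lists: `ct` (8-bit matrix), `sketch`
#'   (binary matrix), `angle_lr`, `angle_ht`, `mirrored`.
#' @export
voi_to_pairs <- function(voi, train_mode = FALSE, window = window_spec(),
                         canny = canny_spec(), size = 128L) {
  slices <- extract_slices(voi, train_mode = train_mode)
  lapply(slices, function(sl) {
    ct <- round_half_up(resize_to_model(apply_window(sl, window), size))
    sk <- canny_edges(ct, canny)
    list(ct = ct, sketch = sk,
         angle_lr = attr(sl, "angle_lr"), angle_ht = attr(sl, "angle_ht"),
         mirrored = attr(sl, "mirrored"))
  })
}

#' Write slice pairs as PNG files with a manifest
#'
#' CT renders are written as 24-bit RGB PNGs (three identical channels),
#' sketches/edges as 8-bit grayscale PNGs; a manifest CSV records the
#' pairing and provenance.
#'
#' @param pairs List of slice pairs from [voi_to_pairs()].
#' @param dir Output directory (created if missing).
#' @param voi_id Identifier used in filenames.
#' @param class_label Optional class column value.
#' @return Data frame manifest (also appended to `dir/manifest.csv`).
#' @export
write_pairs <- function(pairs, dir, voi_id, class_label = NA_character_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    stem <- sprintf("%s_%03d", voi_id, i)
    ct_path <- file.path(dir, paste0(stem, "_ct.png"))
    sk_path <- file.path(dir, paste0(stem, "_sketch.png"))
    ctn <- p$ct / 255
    png::writePNG(array(rep(ctn, 3L), c(dim(p$ct), 3L)), ct_path)
    png::writePNG(p$sketch / 255, sk_path)
    data.frame(ct_path = ct_path, sketch_path = sk_path, voi_id = voi_id,
               angle_lr = p$angle_lr, angle_ht = p$angle_ht,
               mirrored = p$mirrored, class = class_label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.table(manifest, mpath, sep = ",", row.names = FALSE,
                     col.names = !file.exists(mpath), append = file.exists(mpath))
  manifest
}

#' Read an image written by [write_pairs()]
#'
#' @param path PNG path.
#' @return 8-bit matrix (first channel for RGB files).
#' @export
read_image_8bit <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  round_half_up(x * 255)
}
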