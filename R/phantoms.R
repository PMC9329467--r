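#' Phantom specification
#'
#' Parameters of a synthetic lung-CT-like volume containing one tumor.
#' Phantoms stand in for clinical scans throughout the package's tests and
#' examples: a soft-tissue-density lobulated ellipsoidal tumor (around
#' 0--60 HU) sits on an air-density lung background (around -850 HU), with
#' optional curvilinear vessels, a chest-wall band (> 0 HU), Gaussian HU
#' noise, and an optional degraded "pneumonia-like" background of raised
#' attenuation and patchy texture. The same spec and seed always produce a
#' bit-identical volume.
#'
#' @param tumor_long_diameter_mm Tumor long-axis diameter in mm (> 0).
#' @param tumor_lobulation Margin lobulation strength in `[0, 1]`.
#' @param n_vessels Number of tubular vessels to draw.
#' @param chest_wall Draw a chest-wall band on one side of the volume.
#' @param background_style `"healthy"` (flat air-density parenchyma) or
#'   `"pneumonia_like"` (raised mean HU plus patchy consolidation).
#' @param noise_sd Standard deviation of additive Gaussian HU noise.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @param texture_amp Amplitude (HU) of intra-tumor texture; together with
#'   `rim_sharpness` this provides the class-distinctive texture surrogate
#'   used by the augmentation harness.
#' @param rim_sharpness Tumor margin sharpness in `[0, 1]`; 1 gives a hard
#'   two-level boundary, lower values a partial-volume-like shell.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor_long_diameter_mm = 20, tumor_lobulation = 0.5,
                         n_vessels = 3L, chest_wall = TRUE,
                         background_style = c("healthy", "pneumonia_like"),
                         noise_sd = 10, seed = 0L,
                         texture_amp = 0, rim_sharpness = 1) {
  background_style <- match.arg(background_style)
  if (!is.finite(tumor_long_diameter_mm) || tumor_long_diameter_mm <= 0)
    stop("tumor_long_diameter_mm must be positive")
  if (tumor_lobulation < 0 || tumor_lobulation > 1)
    stop("tumor_lobulation must be in [0, 1]")
  if (n_vessels < 0) stop("n_vessels must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(tumor_long_diameter_mm = tumor_long_diameter_mm,
                 tumor_lobulation = tumor_lobulation,
                 n_vessels = as.integer(n_vessels),
                 chest_wall = isTRUE(chest_wall),
                 background_style = background_style,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 texture_amp = texture_amp, rim_sharpness = rim_sharpness),
            class = "phantom_spec")
}

HU_LUNG_HEALTHY <- -850
HU_LUNG_PNEUMONIA <- -680
HU_TUMOR <- 30
HU_VESSEL <- -50
HU_WALL <- 40
HU_AIR <- -1000

#' Generate a synthetic annotated CT volume
#'
#' Renders the phantom described by a [phantom_spec()] on an anisotropic
#' voxel grid (default 0.625 x 0.625 x 0.5 mm, emulating thin-slice chest
#' CT) whose physical extent is three times the tumor long diameter. The
#' returned annotation (tumor center voxel and long diameter) matches the
#' drawn tumor; the binary tumor mask is attached for downstream use.
#'
#' @param spec A [phantom_spec()].
#' @param spacing_mm Voxel spacing (mm), length-3.
#' @return An `annotated_volume`: list with `voxels` (3D HU array),
#'   `spacing_mm`, `tumor_center_voxel`, `tumor_long_diameter_mm`,
#'   `tumor_mask`.
#' @export
make_phantom <- function(spec, spacing_mm = c(0.625, 0.625, 0.5)) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  if (any(spacing_mm <= 0)) stop("spacing components must be positive")
  d <- spec$tumor_long_diameter_mm
  ext <- 2.6 * d                                # physical side, mm
  dims <- pmax(as.integer(round(ext / spacing_mm)), 9L)
  ctr <- (dims + 1L) %/% 2L
  local_seed(spec$seed, {
    # fixed draw order so style/option toggles never shift the tumor shape
    lobf <- value_noise_3d(dims, ncoarse = 5L)          # lobulation field
    texf <- value_noise_3d(dims, ncoarse = 9L)          # intra-tumor texture
    bgf <- value_noise_3d(dims, ncoarse = 5L)           # consolidation patches
    axes_frac <- stats::runif(2, 0.65, 0.85)            # short semi-axes / long
    vess <- replicate(max(spec$n_vessels, 1L), list(
      origin = stats::runif(3, -0.8, 0.8) * d,
      dir = {
        u <- stats::rnorm(3); u / sqrt(sum(u^2))
      },
      bend = stats::rnorm(3, sd = 0.15),
      radius = stats::runif(1, 0.6, 1.1)
    ), simplify = FALSE)
    wall_phase <- stats::runif(1, 0, 2 * pi)
    noise <- if (spec$noise_sd > 0) stats::rnorm(prod(dims), sd = spec$noise_sd) else 0

    # mm coordinates relative to tumor center
    xs <- (seq_len(dims[1]) - ctr[1]) * spacing_mm[1]
    ys <- (seq_len(dims[2]) - ctr[2]) * spacing_mm[2]
    zs <- (seq_len(dims[3]) - ctr[3]) * spacing_mm[3]
    X <- array(rep(xs, times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

    vox <- array(if (spec$background_style == "healthy") HU_LUNG_HEALTHY
                 else HU_LUNG_PNEUMONIA, dims)
    if (spec$background_style == "pneumonia_like") {
      patch <- pmin(pmax((bgf - 0.25) / 0.35, 0), 1)    # smoothstep-ish ramp
      vox <- vox + 80 * patch
    }

    # vessels: curvilinear tubes rasterised as spheres along the curve
    if (spec$n_vessels > 0) {
      for (vz in vess[seq_len(spec$n_vessels)]) {
        tpar <- seq(-1, 1, length.out = 160L)
        pts <- t(vapply(tpar, function(t)
          vz$origin + t * 1.4 * d * vz$dir + t^2 * d * vz$bend, numeric(3)))
        vi <- round(sweep(pts, 2, spacing_mm, "/") + matrix(ctr, nrow(pts), 3, byrow = TRUE))
        rad <- pmax(1L, as.integer(round(vz$radius / spacing_mm)))
        keep <- vi[, 1] >= 1 & vi[, 1] <= dims[1] & vi[, 2] >= 1 & vi[, 2] <= dims[2] &
          vi[, 3] >= 1 & vi[, 3] <= dims[3]
        vi <- vi[keep, , drop = FALSE]
        if (nrow(vi) == 0) next
        off <- expand.grid(a = -rad[1]:rad[1], b = -rad[2]:rad[2], c = -rad[3]:rad[3])
        off <- off[(off$a * spacing_mm[1])^2 + (off$b * spacing_mm[2])^2 +
                     (off$c * spacing_mm[3])^2 <= vz$radius^2, , drop = FALSE]
        for (k in seq_len(nrow(off))) {
          ii <- cbind(vi[, 1] + off$a[k], vi[, 2] + off$b[k], vi[, 3] + off$c[k])
          ok <- ii[, 1] >= 1 & ii[, 1] <= dims[1] & ii[, 2] >= 1 & ii[, 2] <= dims[2] &
            ii[, 3] >= 1 & ii[, 3] <= dims[3]
          vox[ii[ok, , drop = FALSE]] <- HU_VESSEL
        }
      }
    }

    # chest wall: band on the -y side with a gently curved boundary
    if (spec$chest_wall) {
      wall_edge <- -0.8 * d + 0.05 * d * sin(X / d * 2 + wall_phase)
      vox[Y < wall_edge] <- HU_WALL
    }

    # lobulated tumor; the perturbation vanishes along the long (x) axis so
    # the rendered long diameter stays at the requested value
    a <- d / 2; b <- axes_frac[1] * a; cc <- axes_frac[2] * a
    q <- sqrt((X / a)^2 + (Y / b)^2 + (Z / cc)^2)
    ux2 <- ifelse(q > 0, (X / a)^2 / pmax(q^2, 1e-12), 0)
    f <- 1 + spec$tumor_lobulation * 0.28 * lobf * (1 - ux2)
    mask <- q <= f
    rimw <- (1 - spec$rim_sharpness) * 0.35
    tumor_hu <- HU_TUMOR + spec$texture_amp * texf
    vox[mask] <- tumor_hu[mask]
    if (rimw > 0) {
      shell <- q > f & q <= f + rimw
      frac <- (q[shell] - f[shell]) / rimw
      vox[shell] <- tumor_hu[shell] * (1 - frac) + vox[shell] * frac
    }

    vox <- vox + noise
    structure(list(voxels = vox, spacing_mm = spacing_mm,
                   tumor_center_voxel = ctr,
                   tumor_long_diameter_mm = d,
                   tumor_mask = mask),
              class = "annotated_volume")
  })
}

#' Measure the rendered tumor long diameter
#'
#' Longest extent of the tumor mask along the long axis, in mm; used to
#' check that rendered phantoms honour their annotation.
#'
#' @param vol An `annotated_volume` with a `tumor_mask`.
#' @return Diameter in mm.
#' @export
measure_tumor_long_diameter <- function(vol) {
  idx <- which(vol$tumor_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  (max(idx[, 1]) - min(idx[, 1]) + 1L) * vol$spacing_mm[1]
}

#' Emulate a hand-drawn sketch from an edge image
#'
#' Degrades a binary edge map the way hand sketches degrade machine edges:
#' structures away from the central lesion are kept only with smoothly
#' varying probability `detail_level` (0 keeps only the tumor-contour
#' neighborhood, 1 keeps everything), and `jitter` adds stroke-thickness
#' variation and patchy erasures. With `detail_level = 1` and `jitter = 0`
#' the input is returned unchanged.
#'
#' @param edge_image Binary matrix (values 0/255 or 0/1).
#' @param detail_level Real in `[0, 1]`.
#' @param seed Integer seed.
#' @param jitter Perturbation strength in `[0, 1]` (default 0.4).
#' @return Binary matrix with values in `{0, 255}`.
#' @export
make_hand_sketch <- function(edge_image, detail_level, seed = 0L, jitter = 0.4) {
  vals <- unique(as.vector(edge_image))
  if (!all(vals %in% c(0, 1, 255))) stop("edge_image must be binary")
  if (detail_level < 0 || detail_level > 1) stop("detail_level must be in [0, 1]")
  e <- (edge_image > 0) * 1L
  n <- dim(e)
  local_seed(seed, {
    keepf <- value_noise_2d(n)                 # smooth keep-probability field
    erasef <- value_noise_2d(n)
    thickf <- value_noise_2d(n)
    cx <- (n[1] + 1) / 2; cy <- (n[2] + 1) / 2
    R <- outer(seq_len(n[1]) - cx, seq_len(n[2]) - cy,
               function(i, j) sqrt(i^2 + j^2))
    lesion_zone <- R <= 0.36 * n[1]            # dilated tumor-contour region
    keep <- lesion_zone | (keepf < detail_level)
    out <- e * keep
    if (jitter > 0) {
      # thickness variation: dilate strokes where the field says so
      grow <- matrix(0L, n[1], n[2])
      for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        grow <- pmax(grow, shift2(out, sh[1], sh[2]))
      }
      out <- pmax(out, grow * (thickf < 0.5 * jitter))
      erase <- !lesion_zone & (erasef < 0.2 * jitter)
      out[erase] <- 0L
    }
    out * 255L
  })
}

# shift matrix contents by (di, dj), zero-filling exposed borders
shift2 <- function(m, di, dj) {
  n <- dim(m)
  out <- matrix(0L, n[1], n[2])
  si <- max(1L, 1L - di):min(n[1], n[1] - di)
  sj <- max(1L, 1L - dj):min(n[2], n[2] - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

PHANTOM_CLASSES <- c("ADC_like", "SCC_like", "SCLC_like")

class_spec_defaults <- function(cls) {
  switch(cls,
    ADC_like = list(lobulation = c(0.6, 0.9), texture_amp = 25, rim_sharpness = 0.3),
    SCC_like = list(lobulation = c(0.3, 0.6), texture_amp = 60, rim_sharpness = 0.7),
    SCLC_like = list(lobulation = c(0.0, 0.2), texture_amp = 8, rim_sharpness = 1.0),
    stop("unknown class"))
}

#' Generate a labeled phantom dataset
#'
#' Produces `n_tumors` annotated volumes with surrogate histology labels
#' cycling over ADC-like, SCC-like and SCLC-like texture classes. The
#' classes differ in margin lobulation, internal texture amplitude and rim
#' sharpness, giving downstream classifiers learnable signal.
#'
#' @param n_tumors Number of tumors (>= 1).
#' @param spec_ranges Optional overrides: list with `diameter_mm` (length-2
#'   range), `noise_sd`, `pneumonia_frac`.
#' @param seed Integer seed.
#' @param spacing_mm Voxel spacing passed to [make_phantom()].
#' @param indices Optional subset of tumor indices to generate; tumor `i` is
#'   identical whether generated alone or as part of the full set, so large
#'   datasets can be streamed one volume at a time.
#' @return List of `list(volume, class)` entries.
#' @export
make_paired_dataset <- function(n_tumors, spec_ranges = NULL, seed = 0L,
                                spacing_mm = c(0.625, 0.625, 0.5),
                                indices = NULL) {
  if (n_tumors < 1) stop("n_tumors must be >= 1")
  rng <- utils::modifyList(list(diameter_mm = c(14, 30), noise_sd = 10,
                                pneumonia_frac = 0.25), spec_ranges %||% list())
  indices <- indices %||% seq_len(n_tumors)
  stopifnot(all(indices >= 1), all(indices <= n_tumors))
  out <- vector("list", length(indices))
  names(out) <- NULL
  for (k in seq_along(indices)) {
    i <- indices[k]
    cls <- PHANTOM_CLASSES[(i - 1L) %% 3L + 1L]
    cd <- class_spec_defaults(cls)
    pars <- local_seed(seed + 131L * i, list(
      d = stats::runif(1, rng$diameter_mm[1], rng$diameter_mm[2]),
      lob = stats::runif(1, cd$lobulation[1], cd$lobulation[2]),
      pneu = stats::runif(1) < rng$pneumonia_frac,
      nv = sample(2:4, 1)
    ))
    sp <- phantom_spec(
      tumor_long_diameter_mm = pars$d,
      tumor_lobulation = pars$lob,
      n_vessels = pars$nv,
      chest_wall = TRUE,
      background_style = if (pars$pneu) "pneumonia_like" else "healthy",
      noise_sd = rng$noise_sd,
      seed = seed + 977L * i,
      texture_amp = cd$texture_amp,
      rim_sharpness = cd$rim_sharpness)
    out[[k]] <- list(volume = make_phantom(sp, spacing_mm = spacing_mm),
                     class = cls, spec = sp)
  }
  out
}

#' Write a phantom volume to disk
#'
#' Writes the volume as NIfTI (`.nii.gz`) with a JSON sidecar holding the
#' tumor annotation and optional class label.
#'
#' @param vol An `annotated_volume`.
#' @param path Output path without extension.
#' @param class_label Optional class string for the sidecar.
#' @return Invisibly, the NIfTI path.
#' @export
write_phantom <- function(vol, path, class_label = NULL) {
  nii <- paste0(path, ".nii.gz")
  img <- RNifti::asNifti(vol$voxels, pixdim = vol$spacing_mm)
  RNifti::writeNifti(img, nii)
  side <- list(center_voxel = as.integer(vol$tumor_center_voxel),
               long_diameter_mm = vol$tumor_long_diameter_mm)
  if (!is.null(class_label)) side$class <- class_label
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(nii)
}

#' Read a phantom volume written by [write_phantom()]
#'
#' @param path Path without extension.
#' @return An `annotated_volume` (without tumor mask); the sidecar class, if
#'   present, is attached as attribute `"class"`.
#' @export
read_phantom <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vol <- structure(list(voxels = array(as.vector(img), dim(img)),
                        spacing_mm = RNifti::pixdim(img),
                        tumor_center_voxel = as.integer(side$center_voxel),
                        tumor_long_diameter_mm = side$long_diameter_mm,
                        tumor_mask = NULL),
                   class = "annotated_volume")
  if (!is.null(side$class)) attr(vol, "class_label") <- side$class
  vol
}
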