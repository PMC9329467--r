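# Image-quality metrics: PSNR/SSIM on 8-bit pairs, FID over feature groups,
# LPIPS over normalized CNN feature maps.

PSNR_CAP_DB <- 99

#' Mean squared error between two images
#' @param f,g Numeric matrices/arrays of identical shape.
#' @return Mean of squared pixel differences.
#' @export
mse <- function(f, g) {
  if (!identical(dim(f), dim(g))) stop("shape mismatch")
  mean((f - g)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(255^2 / MSE)` for 8-bit-range images. Identical images have
#' infinite PSNR; it is reported as the documented sentinel cap of 99 dB so
#' that aggregate means stay finite.
#'
#' @inheritParams mse
#' @return PSNR in dB.
#' @export
psnr <- function(f, g) {
  m <- mse(f, g)
  if (m == 0) return(PSNR_CAP_DB)
  min(10 * log10(255^2 / m), PSNR_CAP_DB)
}

#' Structural similarity (global statistics)
#'
#' The single-window form computed from image-wide means, variances and
#' covariance with constants `C1 = 0.01 * 255^2`, `C2 = 0.03 * 255^2`
#' (taken verbatim; note some conventions square the whole product `K * L`
#' instead). Variances are population moments. A sliding-window mean is
#' available via `window`.
#'
#' @inheritParams mse
#' @param window Optional odd window side; when given, the mean of local
#'   SSIM values over all fully contained windows is returned.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(f, g, window = NULL) {
  if (!identical(dim(f), dim(g))) stop("shape mismatch")
  C1 <- 0.01 * 255^2
  C2 <- 0.03 * 255^2
  one <- function(fv, gv) {
    muf <- mean(fv); mug <- mean(gv)
    vf <- mean((fv - muf)^2); vg <- mean((gv - mug)^2)
    cfg <- mean((fv - muf) * (gv - mug))
    ((2 * muf * mug + C1) * (2 * cfg + C2)) /
      ((muf^2 + mug^2 + C1) * (vf + vg + C2))
  }
  if (is.null(window)) return(one(f, g))
  n <- dim(f); w <- window
  vals <- c()
  for (i in seq_len(n[1] - w + 1L)) {
    for (j in seq_len(n[2] - w + 1L)) {
      vals <- c(vals, one(f[i:(i + w - 1L), j:(j + w - 1L)],
                          g[i:(i + w - 1L), j:(j + w - 1L)]))
    }
  }
  mean(vals)
}

sqrtm_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- e$values
  ev[ev < -1e-8] <- 0
  ev <- pmax(ev, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Frechet distance between two feature groups
#'
#' `||mu_F - mu_G||^2 + Tr(S_F + S_G - 2 (S_F S_G)^(1/2))`, with the matrix
#' square root evaluated on the symmetrised product
#' `S_F^(1/2) S_G S_F^(1/2)` and tiny negative eigenvalues clipped to zero.
#'
#' @param features_f,features_g Numeric matrices, one row per image, same
#'   number of columns; each group needs at least 2 rows.
#' @return Nonnegative scalar distance.
#' @export
fid <- function(features_f, features_g) {
  features_f <- as.matrix(features_f); features_g <- as.matrix(features_g)
  if (ncol(features_f) != ncol(features_g)) stop("feature dimension mismatch")
  if (nrow(features_f) < 2L || nrow(features_g) < 2L)
    stop("FID requires at least 2 samples per group")
  muf <- colMeans(features_f); mug <- colMeans(features_g)
  Sf <- stats::cov(features_f); Sg <- stats::cov(features_g)
  Sfh <- sqrtm_sym(Sf)
  covterm <- sqrtm_sym(Sfh %*% Sg %*% Sfh)
  sum((muf - mug)^2) + sum(diag(Sf)) + sum(diag(Sg)) - 2 * sum(diag(covterm))
}

#' Deterministic small CNN feature extractor
#'
#' A fixed-seed randomly initialised CNN used as the desk-scale feature
#' backbone for FID and LPIPS: 3x3 stride-2 convolutions with leaky-ReLU,
#' channel widths doubling from `base_channels`. Random CNN features are a
#' recognised lightweight stand-in for pretrained perceptual backbones;
#' loading pretrained weights into the same interface is possible via
#' `layers`.
#'
#' @param n_layers Number of conv stages (default 3).
#' @param base_channels First-stage channels (default 8).
#' @param seed Weight seed (fixed default 7 so all reports share one
#'   backbone).
#' @param layers Optional externally supplied list of `(W, b)` stages.
#' @return A `feature_extractor`: list with `forward(img)` returning the
#'   per-stage feature maps and `pool(img)` returning the final stage's
#'   per-channel spatial mean and standard deviation (`feature_dim = 2 x`
#'   last-stage channels).
#' @export
small_cnn_extractor <- function(n_layers = 3L, base_channels = 8L, seed = 7L,
                                layers = NULL) {
  if (is.null(layers)) {
    layers <- local_seed(seed, {
      cin <- 1L
      lapply(seq_len(n_layers), function(i) {
        cout <- base_channels * 2L^(i - 1L)
        # He-scaled init keeps activation variance alive through the stack;
        # under-scaled weights would collapse pooled features onto the biases
        l <- list(W = array(stats::rnorm(9L * cin * cout,
                                         sd = sqrt(2 / (9 * cin))),
                            c(3L, 3L, cin, cout)),
                  b = stats::rnorm(cout, sd = 0.1))
        cin <<- cout
        l
      })
    })
  }
  feature_dim <- 2L * dim(layers[[length(layers)]]$W)[4]
  fwd <- function(img) {
    x <- as_batch(img_to_model(img))
    maps <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      x <- ag_lrelu(ag_conv2d(x, layers[[i]]$W, layers[[i]]$b,
                              stride = 2L, pad = 1L), 0.2)
      maps[[i]] <- x[, , , 1L, drop = TRUE]
      if (is.null(dim(maps[[i]]))) dim(maps[[i]]) <- c(dim(x)[1], dim(x)[2], dim(x)[3])
    }
    maps
  }
  structure(list(
    name = sprintf("small_cnn_%dx%d_seed%d", n_layers, base_channels, seed),
    feature_dim = feature_dim,
    layers = layers,
    forward = fwd,
    pool = function(img) {
      mp <- fwd(img)
      last <- matrix(mp[[length(mp)]], ncol = dim(mp[[length(mp)]])[3])
      # first and second spatial moments per channel: texture-sensitive
      c(colMeans(last), sqrt(pmax(colMeans(last^2) - colMeans(last)^2, 0)))
    }
  ), class = "feature_extractor")
}

# channel-unit-normalise a (H, W, C) feature map at each spatial location
unit_normalize_map <- function(m) {
  d <- dim(m)
  nrm <- sqrt(apply(m^2, c(1, 2), sum)) + 1e-10
  m / array(rep(nrm, d[3]), d)
}

#' Learned-perceptual-style image patch similarity
#'
#' Feature maps from every stage of `extractor` are channel-unit-normalised
#' and differenced; squared differences are channel-weighted by `weights`
#' (uniform by default), averaged over each map and summed over stages.
#' Zero iff the inputs are identical (with positive weights).
#'
#' @inheritParams mse
#' @param extractor A [small_cnn_extractor()]-style feature extractor.
#' @param weights Optional list of per-stage channel weight vectors.
#' @param normalize Channel-unit-normalise the feature maps before
#'   differencing (default TRUE, the standard perceptual-metric convention);
#'   FALSE compares raw feature maps.
#' @return Nonnegative scalar.
#' @export
lpips <- function(f, g, extractor = small_cnn_extractor(), weights = NULL,
                  normalize = TRUE) {
  if (!identical(dim(f), dim(g))) stop("shape mismatch")
  mf <- extractor$forward(f)
  mg <- extractor$forward(g)
  if (!is.null(weights) && length(weights) != length(mf))
    stop("weights must have one vector per extractor stage")
  tot <- 0
  for (l in seq_along(mf)) {
    a <- if (normalize) unit_normalize_map(mf[[l]]) else mf[[l]]
    b <- if (normalize) unit_normalize_map(mg[[l]]) else mg[[l]]
    w <- if (is.null(weights)) rep(1, dim(a)[3]) else weights[[l]]
    if (length(w) != dim(a)[3]) stop("weight length mismatch at stage ", l)
    dif <- (a - b) * array(rep(w, each = dim(a)[1] * dim(a)[2]), dim(a))
    tot <- tot + sum(dif^2) / (dim(a)[1] * dim(a)[2])
  }
  tot
}

#' Evaluate a generated image set against its references
#'
#' PSNR, SSIM and LPIPS are computed per index-aligned pair and averaged;
#' FID is computed once between the pooled-feature groups of the two sets.
#'
#' @param real_set,generated_set Lists of 8-bit image matrices, same length
#'   (>= 2 for the group FID).
#' @param extractor Feature extractor for FID/LPIPS.
#' @return A `metric_report`: list with `psnr_mean`, `ssim_mean`,
#'   `lpips_mean`, `fid`, `n_pairs`.
#' @export
evaluate_images <- function(real_set, generated_set,
                            extractor = small_cnn_extractor()) {
  if (length(real_set) != length(generated_set)) stop("set length mismatch")
  n <- length(real_set)
  if (n < 2L) stop("FID requires at least 2 images per group")
  ps <- ss <- lp <- numeric(n)
  for (i in seq_len(n)) {
    ps[i] <- psnr(real_set[[i]], generated_set[[i]])
    ss[i] <- ssim(real_set[[i]], generated_set[[i]])
    lp[i] <- lpips(real_set[[i]], generated_set[[i]], extractor)
  }
  ff <- t(vapply(real_set, extractor$pool, numeric(extractor$feature_dim)))
  fg <- t(vapply(generated_set, extractor$pool, numeric(extractor$feature_dim)))
  structure(list(psnr_mean = mean(ps), ssim_mean = mean(ss),
                 lpips_mean = mean(lp), fid = fid(ff, fg), n_pairs = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report over %d pairs\n", x$n_pairs))
  cat(sprintf("  PSNR  %7.3f dB\n  SSIM  %7.4f\n  LPIPS %7.4f\n  FID   %7.2f\n",
              x$psnr_mean, x$ssim_mean, x$lpips_mean, x$fid))
  invisible(x)
}
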