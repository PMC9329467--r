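#' Canny edge-detector specification
#'
#' The four-step detector used to derive sketch surrogates from windowed CT
#' renders: (1) Gaussian smoothing with a fixed 5x5 kernel, (2) Sobel
#' gradients, (3) non-maximum suppression along the gradient normal, (4)
#' hysteresis thresholding with limits 128 (lower) and 200 (upper) on the
#' gradient magnitude.
#'
#' @param gaussian_kernel Odd kernel side (default 5).
#' @param low_threshold Lower hysteresis limit (default 128).
#' @param high_threshold Upper hysteresis limit (default 200).
#' @param sigma Gaussian standard deviation in pixels (default 1.1, the
#'   conventional value for a 5x5 support).
#' @return List of class `canny_spec`.
#' @export
canny_spec <- function(gaussian_kernel = 5L, low_threshold = 128,
                       high_threshold = 200, sigma = 1.1) {
  if (gaussian_kernel %% 2L != 1L) stop("gaussian_kernel must be odd")
  if (!(low_threshold >= 0 && low_threshold < high_threshold && high_threshold <= 255))
    stop("thresholds must satisfy 0 <= low < high <= 255")
  structure(list(gaussian_kernel = as.integer(gaussian_kernel),
                 low_threshold = low_threshold,
                 high_threshold = high_threshold, sigma = sigma),
            class = "canny_spec")
}

gaussian_kernel_2d <- function(k, sigma) {
  h <- (k - 1L) %/% 2L
  g <- stats::dnorm(-h:h, sd = sigma)
  g <- g / sum(g)
  outer(g, g)
}

# Direct 2D correlation with replicate borders. Exact (non-FFT) arithmetic:
# non-maximum suppression compares gradients with strict inequalities, so
# round-off noise on flat regions would otherwise flip edge decisions.
filt2 <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- kh %/% 2L; pw <- kw %/% 2L
  H <- nrow(img); W <- ncol(img)
  p <- img[pmin(pmax(seq_len(H + 2L * ph) - ph, 1L), H),
           pmin(pmax(seq_len(W + 2L * pw) - pw, 1L), W)]
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kern[a, b] == 0) next
      out <- out + kern[a, b] * p[a:(a + H - 1L), b:(b + W - 1L)]
    }
  }
  out
}

#' Canny edge detection
#'
#' Runs the pinned four-step pipeline of [canny_spec()] on an 8-bit
#' grayscale image and returns a binary edge map. Non-maximum suppression
#' quantises the gradient direction to four bins; hysteresis keeps weak
#' edge pixels (magnitude above the lower limit) only when 8-connected to a
#' strong pixel (above the upper limit).
#'
#' @param ct_image_8bit Numeric matrix in `[0, 255]`.
#' @param spec A [canny_spec()].
#' @return Binary matrix with values in `{0, 255}`.
#' @export
canny_edges <- function(ct_image_8bit, spec = canny_spec()) {
  if (!inherits(spec, "canny_spec")) stop("spec must be a canny_spec")
  img <- ct_image_8bit
  sm <- filt2(img, gaussian_kernel_2d(spec$gaussian_kernel, spec$sigma))
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)  # d/d(row)
  gi <- filt2(sm, sob)
  gj <- filt2(sm, t(sob))
  m <- sqrt(gi^2 + gj^2)
  # quantised non-maximum suppression
  a <- atan2(gi, gj)
  a[a < 0] <- a[a < 0] + pi
  bin <- floor((a + pi / 8) / (pi / 4)) %% 4
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (bq in 0:3) {
    d <- nb[[bq + 1L]]
    n1 <- shift2(m, -d[1], -d[2])
    n2 <- shift2(m, d[1], d[2])
    keep <- keep | (bin == bq & m > n1 & m >= n2)
  }
  strong <- keep & m > spec$high_threshold
  weak <- keep & m > spec$low_threshold
  # hysteresis: grow strong set through 8-connected weak pixels
  repeat {
    grow <- strong
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      grow <- grow | (shift2(strong, di, dj) & weak)
    }
    if (identical(grow, strong)) break
    strong <- grow
  }
  strong * 255L
}
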