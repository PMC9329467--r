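# Shared helpers: seeded evaluation, image scaling, half-up rounding.

# Evaluate `code` under a temporary RNG state; the caller's stream is
# untouched. All stochastic package operations route through this so a
# single integer seed makes a whole pipeline bit-reproducible.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# [0,255] 8-bit <-> [-1,1] model range
img_to_model <- function(x) x / 127.5 - 1
model_to_img <- function(x) round_half_up(pmin(pmax(x, -1), 1) * 127.5 + 127.5)

# [0,255] sketch -> [0,1] condition channel
sketch_to_model <- function(x) x / 255

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# Vectorised trilinear interpolation of a 3D array at fractional voxel
# coordinates (1-based). Coordinates are clamped to the volume (nearest-
# border padding).
interp_trilinear <- function(v, xi, yi, zi) {
  d <- dim(v)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2]); zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L); z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(xi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  lin <- function(a, b, c) a + d[1] * (b - 1) + d[1] * d[2] * (c - 1)
  v000 <- v[lin(x0, y0, z0)]; v100 <- v[lin(x1, y0, z0)]
  v010 <- v[lin(x0, y1, z0)]; v110 <- v[lin(x1, y1, z0)]
  v001 <- v[lin(x0, y0, z1)]; v101 <- v[lin(x1, y0, z1)]
  v011 <- v[lin(x0, y1, z1)]; v111 <- v[lin(x1, y1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Linear-interpolation weight matrix mapping `nc` coarse samples to `n`
# evenly spaced fine samples.
interp_weights <- function(n, nc) {
  s <- seq(1, nc, length.out = n)
  i0 <- pmin(floor(s), nc - 1L)
  f <- s - i0
  W <- matrix(0, n, nc)
  W[cbind(seq_len(n), i0)] <- 1 - f
  W[cbind(seq_len(n), i0 + 1L)] <- f
  W
}

# Smooth 3D value noise in [-1, 1]-ish range: a coarse uniform grid
# trilinearly upsampled to `dims` (separable, three matmuls). Consumes RNG
# state.
value_noise_3d <- function(dims, ncoarse = 6L) {
  nc <- ncoarse
  g <- array(stats::runif(nc^3, -1, 1), rep(nc, 3L))
  A <- interp_weights(dims[1], nc); B <- interp_weights(dims[2], nc)
  C <- interp_weights(dims[3], nc)
  g1 <- A %*% matrix(g, nc, nc * nc)                       # (d1, nc*nc)
  g2 <- B %*% matrix(aperm(array(g1, c(dims[1], nc, nc)), c(2, 1, 3)), nc)
  g3 <- C %*% matrix(aperm(array(g2, c(dims[2], dims[1], nc)), c(3, 2, 1)), nc)
  aperm(array(g3, c(dims[3], dims[1], dims[2])), c(2, 3, 1))
}

# Smooth 2D value noise in [0, 1]: coarse uniform grid, bilinearly upsampled.
value_noise_2d <- function(dims, ncoarse = 8L) {
  g <- array(stats::runif(ncoarse^2 * 2), c(ncoarse, ncoarse, 2L))
  sx <- seq(1, ncoarse, length.out = dims[1])
  sy <- seq(1, ncoarse, length.out = dims[2])
  co <- expand.grid(x = sx, y = sy)
  matrix(interp_trilinear(g, co$x, co$y, rep(1, nrow(co))), dims[1], dims[2])
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what))
  invisible(x)
}
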