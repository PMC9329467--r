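# Independent reference implementations used as test oracles.

# numpy implementation of the pinned 4-step Canny pipeline (5x5 Gaussian,
# Sobel, quantised NMS, 8-connected hysteresis), written independently of
# the R code path and executed through the system python.
PY_CANNY <- '
import sys, numpy as np

def gauss_kernel(k=5, sigma=1.1):
    ax = np.arange(k) - k // 2
    g = np.exp(-ax**2 / (2 * sigma**2))
    g = g / g.sum()
    return np.outer(g, g)

def conv2_replicate(img, k):
    kh, kw = k.shape
    ph, pw = kh // 2, kw // 2
    p = np.pad(img, ((ph, ph), (pw, pw)), mode="edge")
    out = np.zeros_like(img, dtype=float)
    for a in range(kh):
        for b in range(kw):
            out += k[a, b] * p[a:a + img.shape[0], b:b + img.shape[1]]
    return out

def canny(img, low=128.0, high=200.0):
    sm = conv2_replicate(img, gauss_kernel())
    sob = np.array([[-1., -2., -1.], [0., 0., 0.], [1., 2., 1.]])
    gi = conv2_replicate(sm, sob)      # along rows
    gj = conv2_replicate(sm, sob.T)    # along cols
    m = np.hypot(gi, gj)
    a = np.arctan2(gi, gj)
    a[a < 0] += np.pi
    bins = np.floor((a + np.pi / 8) / (np.pi / 4)).astype(int) % 4
    offs = {0: (0, 1), 1: (1, 1), 2: (1, 0), 3: (1, -1)}
    H, W = m.shape
    keep = np.zeros((H, W), dtype=bool)
    def shifted(mat, di, dj):
        out = np.zeros_like(mat)
        si0, si1 = max(0, -di), min(H, H - di)
        sj0, sj1 = max(0, -dj), min(W, W - dj)
        out[si0 + di:si1 + di, sj0 + dj:sj1 + dj] = mat[si0:si1, sj0:sj1]
        return out
    for b, (di, dj) in offs.items():
        n1 = shifted(m, -di, -dj)
        n2 = shifted(m, di, dj)
        keep |= (bins == b) & (m > n1) & (m >= n2)
    strong = keep & (m > high)
    weak = keep & (m > low)
    while True:
        grow = strong.copy()
        for di in (-1, 0, 1):
            for dj in (-1, 0, 1):
                if di == 0 and dj == 0:
                    continue
                grow |= shifted(strong, di, dj).astype(bool) & weak
        if (grow == strong).all():
            break
        strong = grow
    return strong

inp, outp = sys.argv[1], sys.argv[2]
with open(inp) as fh:
    n = int(fh.readline())
    res = []
    for _ in range(n):
        h, w = map(int, fh.readline().split())
        vals = np.array(fh.readline().split(), dtype=float).reshape(h, w)
        res.append(canny(vals))
with open(outp, "w") as fh:
    fh.write(f"{len(res)}\\n")
    for r in res:
        fh.write(f"{r.shape[0]} {r.shape[1]}\\n")
        fh.write(" ".join("1" if v else "0" for v in r.ravel()) + "\\n")
'

# images: list of numeric matrices -> list of logical matrices
py_canny_reference <- function(images) {
  td <- tempfile("canny")
  dir.create(td)
  script <- file.path(td, "canny_ref.py")
  writeLines(PY_CANNY, script)
  inp <- file.path(td, "in.txt"); outp <- file.path(td, "out.txt")
  con <- file(inp, "w")
  writeLines(as.character(length(images)), con)
  for (im in images) {
    writeLines(paste(nrow(im), ncol(im)), con)
    # python reads row-major: transpose so rows stream first
    writeLines(paste(as.vector(t(im)), collapse = " "), con)
  }
  close(con)
  status <- system2("python", c(script, inp, outp), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outp)) stop("python canny oracle failed: ", paste(status, collapse = "\n"))
  lines <- readLines(outp)
  n <- as.integer(lines[1])
  out <- vector("list", n)
  k <- 2L
  for (i in seq_len(n)) {
    hw <- as.integer(strsplit(lines[k], " ")[[1]]); k <- k + 1L
    v <- as.integer(strsplit(lines[k], " ")[[1]]); k <- k + 1L
    out[[i]] <- matrix(v == 1L, hw[1], hw[2], byrow = TRUE)
  }
  out
}

# central finite-difference gradient of scalar-valued f at array x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
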