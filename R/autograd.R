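# Reverse-mode autodiff core.
#
# Tensors are plain R arrays; image batches use dim (H, W, C, N) and dense
# features dim (F, N). A graph node is an environment holding the value, an
# accumulated gradient, its parents and a backward closure. Node creation
# order is a valid topological order of the dynamically built DAG, so
# backward() just walks ids in descending order. Every op accepts either a
# node or a raw array; when no input requires gradients the op returns a raw
# array, so inference-mode forwards carry no graph overhead.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 1L
.ag$geom <- new.env(parent = emptyenv())   # im2col geometry cache

is_ag_node <- function(x) inherits(x, "ag_node")

#' @noRd
ag_value <- function(x) if (is_ag_node(x)) x$value else x

ag_leaf <- function(value, requires_grad = TRUE) {
  n <- new.env(parent = emptyenv())
  n$id <- .ag$counter; .ag$counter <- .ag$counter + 1L
  n$value <- value
  n$grad <- NULL
  n$requires <- requires_grad
  n$parents <- list()
  n$backward <- NULL
  class(n) <- "ag_node"
  n
}

# Build an op node. `backward` is function(g) returning a list of gradients
# aligned with `parents` (NULL entries allowed for non-node / non-requiring
# parents). Returns a raw array when nothing in `parents` requires grad.
ag_op <- function(value, parents, backward) {
  req <- vapply(parents, function(p) is_ag_node(p) && p$requires, logical(1))
  if (!any(req)) return(value)
  n <- ag_leaf(value, requires_grad = TRUE)
  n$parents <- parents
  n$needs <- req
  n$backward <- backward
  n
}

#' @noRd
ag_backward <- function(out, seed = 1) {
  stopifnot(is_ag_node(out))
  # collect ancestors (iterative DFS), clear grads
  stack <- list(out)
  nodes <- list()
  seen <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (nd$id %in% seen) next
    seen <- c(seen, nd$id)
    nodes[[length(nodes) + 1L]] <- nd
    nd$grad <- NULL
    for (p in nd$parents) if (is_ag_node(p) && p$requires) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  out$grad <- if (length(seed) == 1L && length(out$value) > 1L)
    array(seed, dim = dim(out$value) %||% length(out$value)) else seed
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!nd$needs[i] || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av + bv, list(a, b), function(g) list(g, if (length(bv) == 1L) sum(g) else g))
}

ag_sub <- function(a, b) {
  ag_op(ag_value(a) - ag_value(b), list(a, b),
        function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, k) {
  ag_op(ag_value(a) * k, list(a), function(g) list(g * k))
}

ag_relu <- function(a) {
  av <- ag_value(a); m <- av > 0
  ag_op(av * m, list(a), function(g) list(g * m))
}

ag_lrelu <- function(a, slope = 0.2) {
  av <- ag_value(a)
  f <- slope + (1 - slope) * (av > 0)
  ag_op(av * f, list(a), function(g) list(g * f))
}

ag_tanh <- function(a) {
  v <- tanh(ag_value(a))
  ag_op(v, list(a), function(g) list(g * (1 - v^2)))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_log <- function(a) {
  av <- ag_value(a)
  ag_op(log(av), list(a), function(g) list(g / av))
}

ag_abs <- function(a) {
  av <- ag_value(a)
  ag_op(abs(av), list(a), function(g) list(g * sign(av)))
}

ag_clamp <- function(a, lo, hi) {
  av <- ag_value(a)
  m <- av >= lo & av <= hi
  ag_op(pmin(pmax(av, lo), hi), list(a), function(g) list(g * m))
}

ag_mean <- function(a) {
  av <- ag_value(a); n <- length(av)
  ag_op(mean(av), list(a), function(g) list(array(g / n, dim = dim(av) %||% n)))
}

ag_sum <- function(a) {
  av <- ag_value(a)
  ag_op(sum(av), list(a), function(g) list(array(g, dim = dim(av) %||% length(av))))
}

## ---- dense ----------------------------------------------------------------

# x: (in, N); W: (out, in); b: (out) or NULL
ag_linear <- function(x, W, b = NULL) {
  xv <- ag_value(x); Wv <- ag_value(W)
  if (is.null(dim(xv))) xv <- matrix(xv, ncol = 1L)
  v <- Wv %*% xv
  if (!is.null(b)) v <- v + ag_value(b)
  ag_op(v, list(x, W, b %||% list()), function(g) {
    list(crossprod(Wv, g), tcrossprod(g, xv), if (!is.null(b)) rowSums(g))
  })
}

## ---- im2col convolution machinery -----------------------------------------

# Geometry for a conv over one padded sample. Row order of the column matrix
# is the (kh, kw, C) array linearisation; the gather index covers one sample
# and is applied to the whole batch by matrix row-indexing (column-major
# layout makes the (K*HW, N) -> (K, HW*N) reinterpretation a free reshape).
conv_geom <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  g <- .ag$geom[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - kh) %/% stride + 1L   # floor: trailing rows that do not fit are dropped
  Wout <- (Wp - kw) %/% stride + 1L
  dyv <- rep.int(0:(kh - 1L), kw * C)
  dxv <- rep.int(rep(0:(kw - 1L), each = kh), C)
  cv <- rep(0:(C - 1L), each = kh * kw)
  rp <- dyv + Hp * dxv + Hp * Wp * cv
  iv <- rep.int(0:(Hout - 1L), Wout)
  jv <- rep(0:(Wout - 1L), each = Hout)
  cp <- stride * iv + Hp * stride * jv
  idx1 <- as.integer(outer(rp, cp, `+`) + 1L)
  g <- list(Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, K = kh * kw * C,
            kh = kh, kw = kw, C = C, stride = stride, pad = pad, idx1 = idx1)
  .ag$geom[[key]] <- g
  g
}

pad_input <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(xp, geom) {
  N <- dim(xp)[4]
  dim(xp) <- c(geom$Hp * geom$Wp * geom$C, N)
  cols <- xp[geom$idx1, , drop = FALSE]
  dim(cols) <- c(geom$K, geom$Hout * geom$Wout * N)
  cols
}

# Scatter-add columns back into a zero padded array; inverse of im2col.
col2im <- function(dcols, geom, N) {
  gpad <- array(0, c(geom$Hp, geom$Wp, geom$C, N))
  dca <- array(dcols, c(geom$kh, geom$kw, geom$C, geom$Hout, geom$Wout, N))
  for (a in seq_len(geom$kh)) {
    ri <- seq.int(a, by = geom$stride, length.out = geom$Hout)
    for (b in seq_len(geom$kw)) {
      ci <- seq.int(b, by = geom$stride, length.out = geom$Wout)
      sl <- dca[a, b, , , , , drop = FALSE]
      dim(sl) <- c(geom$C, geom$Hout, geom$Wout, N)
      gpad[ri, ci, , ] <- gpad[ri, ci, , , drop = FALSE] + aperm(sl, c(2, 3, 1, 4))
    }
  }
  gpad
}

unpad_grad <- function(gpad, pad, H, W) {
  if (pad == 0L) return(gpad)
  gpad[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

cols_to_chw <- function(outmat, Cout, Hout, Wout, N) {
  aperm(array(outmat, c(Cout, Hout, Wout, N)), c(2, 3, 1, 4))
}

chw_to_cols <- function(y) {
  d <- dim(y)
  matrix(aperm(y, c(3, 1, 2, 4)), nrow = d[3])
}

# x: (H,W,Cin,N); W: (kh,kw,Cin,Cout); b: (Cout) or NULL
ag_conv2d <- function(x, W, b = NULL, stride = 2L, pad = 1L) {
  xv <- ag_value(x); Wv <- ag_value(W)
  d <- dim(xv); dk <- dim(Wv)
  stopifnot(d[3] == dk[3])
  geom <- conv_geom(d[1], d[2], d[3], dk[1], dk[2], as.integer(stride), as.integer(pad))
  Cout <- dk[4]
  Wmat <- matrix(Wv, nrow = geom$K)
  cols <- im2col(pad_input(xv, geom$pad), geom)
  out <- crossprod(Wmat, cols)
  if (!is.null(b)) out <- out + ag_value(b)
  v <- cols_to_chw(out, Cout, geom$Hout, geom$Wout, d[4])
  ag_op(v, list(x, W, b %||% list()), function(g) {
    gmat <- chw_to_cols(g)
    dx <- NULL
    if (is_ag_node(x) && x$requires) {
      dx <- unpad_grad(col2im(Wmat %*% gmat, geom, d[4]), geom$pad, d[1], d[2])
    }
    dW <- array(tcrossprod(cols, gmat), dim = dk)
    list(dx, dW, if (!is.null(b)) rowSums(gmat))
  })
}

# Transposed conv (up-convolution), fixed kernel-4/stride-2/pad-1 geometry:
# (H,W,Cin,N) -> (2H,2W,Cout,N). Weights stored as (kh,kw,Cout,Cin), i.e. in
# the layout of the adjoint conv that maps the large image back down.
ag_tconv2d <- function(x, W, b = NULL) {
  xv <- ag_value(x); Wv <- ag_value(W)
  d <- dim(xv); dk <- dim(Wv)
  Cout <- dk[3]; Cin <- dk[4]
  stopifnot(d[3] == Cin)
  Ho <- 2L * d[1]; Wo <- 2L * d[2]
  geom <- conv_geom(Ho, Wo, Cout, dk[1], dk[2], 2L, 1L)
  stopifnot(geom$Hout == d[1], geom$Wout == d[2])
  Wmat <- matrix(Wv, nrow = geom$K)
  zmat <- chw_to_cols(xv)                      # (Cin, H*W*N)
  ypad <- col2im(Wmat %*% zmat, geom, d[4])
  y <- unpad_grad(ypad, geom$pad, Ho, Wo)
  dim(y) <- c(Ho, Wo, Cout, d[4])
  if (!is.null(b)) y <- y + rep(ag_value(b), each = Ho * Wo)
  ag_op(y, list(x, W, b %||% list()), function(g) {
    cols_g <- im2col(pad_input(g, geom$pad), geom)
    dxmat <- crossprod(Wmat, cols_g)           # (Cin, H*W*N)
    dx <- cols_to_chw(dxmat, Cin, d[1], d[2], d[4])
    dW <- array(tcrossprod(cols_g, zmat), dim = dk)
    db <- if (!is.null(b)) colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = Cout))
    list(dx, dW, db)
  })
}

## ---- style-modulated convolution ------------------------------------------

# broadcast a (C, N) matrix over the spatial dims of an (H, W, C, N) array
bc_cn <- function(M, H, W) array(rep(as.vector(M), each = H * W),
                                 c(H, W, nrow(M), ncol(M)))
# reduce an (H, W, C, N) array over its spatial dims to (C, N)
rs_cn <- function(A) {
  d <- dim(A)
  matrix(colSums(matrix(A, nrow = d[1] * d[2])), d[3], d[4])
}

# Style-modulated convolution, stride 1, half-kernel padding.
# Modulating the kernel per input channel is equivalent to scaling the input
# channels per sample and convolving once with the shared kernel; the
# demodulation factor per (output channel, sample) is
# g[o,n] = 1/sqrt(sum_i K2[i,o] s[i,n]^2 + eps), K2[i,o] = sum_kernel k^2.
# This fused form allows a single batched im2col for the whole minibatch.
ag_modconv2d <- function(x, W, s, b = NULL, demodulate = TRUE, eps = 1e-8) {
  xv <- ag_value(x); Wv <- ag_value(W); sv <- ag_value(s)
  if (is.null(dim(sv))) sv <- matrix(sv, ncol = dim(xv)[4])
  d <- dim(xv); dk <- dim(Wv)
  stopifnot(d[3] == dk[3], nrow(sv) == dk[3], ncol(sv) == d[4])
  kh <- dk[1]; kw <- dk[2]; Cin <- dk[3]; Cout <- dk[4]; N <- d[4]
  geom <- conv_geom(d[1], d[2], Cin, kh, kw, 1L, (kh - 1L) %/% 2L)
  Wmat <- matrix(Wv, nrow = geom$K)
  sfull <- bc_cn(sv, d[1], d[2])
  xs <- xv * sfull
  cols <- im2col(pad_input(xs, geom$pad), geom)
  cmat <- crossprod(Wmat, cols)                       # (Cout, H*W*N)
  cc <- cols_to_chw(cmat, Cout, geom$Hout, geom$Wout, N)
  if (demodulate) {
    K2 <- matrix(colSums(matrix(Wv^2, nrow = kh * kw)), Cin, Cout)
    q <- crossprod(K2, sv^2) + eps                    # (Cout, N)
    gfac <- 1 / sqrt(q)
    y <- cc * bc_cn(gfac, geom$Hout, geom$Wout)
  } else y <- cc
  if (!is.null(b)) y <- y + rep(ag_value(b), each = geom$Hout * geom$Wout)
  ag_op(y, list(x, W, s, b %||% list()), function(g) {
    if (demodulate) {
      dc <- g * bc_cn(gfac, geom$Hout, geom$Wout)
      G1 <- rs_cn(g * cc)                             # (Cout, N)
      dq <- -0.5 * gfac^3 * G1
    } else dc <- g
    dcmat <- chw_to_cols(dc)
    dW <- array(tcrossprod(cols, dcmat), dim = dk)
    dxs <- unpad_grad(col2im(Wmat %*% dcmat, geom, N), geom$pad, d[1], d[2])
    dim(dxs) <- d
    ds <- rs_cn(dxs * xv)
    if (demodulate) {
      dK2 <- tcrossprod(sv^2, dq)                     # (Cin, Cout)
      dW <- dW + 2 * Wv * rep(as.vector(dK2), each = kh * kw)
      ds <- ds + 2 * sv * (K2 %*% dq)
    }
    dx <- if (is_ag_node(x) && x$requires) dxs * sfull
    db <- if (!is.null(b)) colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = Cout))
    list(dx, dW, ds, db)
  })
}

## ---- structural ops --------------------------------------------------------

ag_concat_c <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db <- dim(bv)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- av
  v[, , da[3] + seq_len(db[3]), ] <- bv
  ag_op(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ag_upsample2 <- function(a) {
  av <- ag_value(a); d <- dim(av)
  key <- paste("up", d[1], d[2], sep = "_")
  ridx <- .ag$geom[[key]]
  if (is.null(ridx)) {
    i2 <- rep(seq_len(d[1]), each = 2L)
    j2 <- rep(seq_len(d[2]), each = 2L)
    ridx <- as.integer(outer(i2, (j2 - 1L) * d[1], `+`))
    .ag$geom[[key]] <- ridx
  }
  vm <- av; dim(vm) <- c(d[1] * d[2], d[3] * d[4])
  v <- vm[ridx, , drop = FALSE]
  dim(v) <- c(2L * d[1], 2L * d[2], d[3], d[4])
  ag_op(v, list(a), function(g) {
    i1 <- seq.int(1L, 2L * d[1], 2L); i2 <- i1 + 1L
    j1 <- seq.int(1L, 2L * d[2], 2L); j2 <- j1 + 1L
    list(g[i1, j1, , , drop = FALSE] + g[i2, j1, , , drop = FALSE] +
         g[i1, j2, , , drop = FALSE] + g[i2, j2, , , drop = FALSE])
  })
}

# Per-channel, per-sample normalisation (instance norm, no affine terms).
ag_instnorm <- function(a, eps = 1e-5) {
  av <- ag_value(a); d <- dim(av)
  m <- d[1] * d[2]
  xm <- matrix(av, nrow = m)                 # columns = (channel, sample)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  v <- colMeans(xc^2)
  isd <- 1 / sqrt(v + eps)
  xh <- xc * rep(isd, each = m)
  ag_op(array(xh, d), list(a), function(g) {
    gm <- matrix(g, nrow = m)
    gmu <- colMeans(gm)
    gxh <- colMeans(gm * xh)
    dx <- (gm - rep(gmu, each = m) - xh * rep(gxh, each = m)) * rep(isd, each = m)
    list(array(dx, d))
  })
}

ag_flatten <- function(a) {
  av <- ag_value(a); d <- dim(av)
  f <- prod(d[1:3])
  ag_op(matrix(av, nrow = f), list(a), function(g) list(array(g, d)))
}

# Mean softmax cross-entropy; logits (K, N), labels integer in 1..K.
ag_softmax_xent <- function(logits, labels) {
  lv <- ag_value(logits)
  K <- nrow(lv); N <- ncol(lv)
  sh <- lv - rep(apply(lv, 2, max), each = K)
  e <- exp(sh)
  p <- e / rep(colSums(e), each = K)
  picked <- p[cbind(labels, seq_len(N))]
  v <- -mean(log(pmax(picked, 1e-12)))
  ag_op(v, list(logits), function(g) {
    oh <- matrix(0, K, N); oh[cbind(labels, seq_len(N))] <- 1
    list(g * (p - oh) / N)
  })
}
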