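# Low-level neural-network operations with hand-derived backward passes.
#
# Internal layouts (column-major friendly):
#   feature maps  : array (H, W, C, B)
#   token blocks  : array (D, N+1, B)
#   vectors       : matrix (width, B)
# Each *_fwd returns list(out, cache); each *_bwd takes (cache, dout) and
# returns list(dx, grads...). All backward passes are finite-difference
# checked in the test suite.

# ---- im2col index cache ------------------------------------------------

im2col_index <- function(Hp, Wp, C, B, kh, kw, stride) {
  key <- paste(Hp, Wp, C, B, kh, kw, stride, sep = "_")
  hit <- .cytoxai_env$im2col[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- (Hp - kh) %/% stride + 1L
  Wout <- (Wp - kw) %/% stride + 1L
  ky <- rep(0:(kh - 1L), times = kw * C)
  kx <- rep(rep(0:(kw - 1L), each = kh), times = C)
  cc <- rep(0:(C - 1L), each = kh * kw)
  row_off <- ky + Hp * kx + Hp * Wp * cc
  oy <- rep(0:(Hout - 1L), times = Wout * B)
  ox <- rep(rep(0:(Wout - 1L), each = Hout), times = B)
  bb <- rep(0:(B - 1L), each = Hout * Wout)
  col_off <- oy * stride + Hp * (ox * stride) + Hp * Wp * C * bb
  idx <- outer(row_off, col_off, "+") + 1L
  res <- list(idx = idx, Hout = Hout, Wout = Wout)
  if (is.null(.cytoxai_env$im2col)) .cytoxai_env$im2col <- list()
  if (length(.cytoxai_env$im2col) > 32L) .cytoxai_env$im2col <- list()
  .cytoxai_env$im2col[[key]] <- res
  res
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# ---- convolution -------------------------------------------------------

# x: (H, W, Cin, B); W_mat: (Cout, kh*kw*Cin) with row order (ky, kx, cin)
conv2d_fwd <- function(x, W_mat, b, kh, kw, stride, pad) {
  d <- dim(x)
  xpad <- pad_spatial(x, pad)
  dp <- dim(xpad)
  ii <- im2col_index(dp[1], dp[2], dp[3], dp[4], kh, kw, stride)
  # index the flattened array: a bare index matrix with ndim columns
  # would trigger coordinate-matrix indexing
  cols <- matrix(as.vector(xpad)[ii$idx], nrow = nrow(ii$idx))
  out_mat <- W_mat %*% cols + b
  out <- aperm(array(out_mat, dim = c(nrow(W_mat), ii$Hout, ii$Wout, d[4])),
               c(2, 3, 1, 4))
  list(out = out,
       cache = list(cols = cols, idx = ii$idx, dim_pad = dp, dim_in = d,
                    W_mat = W_mat, kh = kh, kw = kw, stride = stride,
                    pad = pad, Hout = ii$Hout, Wout = ii$Wout))
}

conv2d_bwd <- function(cache, dout) {
  dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = nrow(cache$W_mat))
  dW <- dmat %*% t(cache$cols)
  db <- rowSums(dmat)
  dcols <- crossprod(cache$W_mat, dmat)
  # scatter-add per kernel offset: within one row of the index matrix the
  # target positions are distinct, so vectorized indexed addition is exact
  dxpad <- array(0, dim = cache$dim_pad)
  for (r in seq_len(nrow(cache$idx))) {
    ii <- cache$idx[r, ]
    dxpad[ii] <- dxpad[ii] + dcols[r, ]
  }
  p <- cache$pad; din <- cache$dim_in
  dx <- if (p > 0L)
    dxpad[p + seq_len(din[1]), p + seq_len(din[2]), , , drop = FALSE]
  else dxpad
  dim(dx) <- din
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# ---- batch normalization (per channel over H, W, B) -------------------
# Training mode uses batch statistics; evaluation uses the running
# mean/variance buffers accumulated during training.

bn_fwd <- function(x, g, beta, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  n <- nrow(m)
  mu <- colMeans(m)
  xc <- m - rep(mu, each = n)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(g, each = n) + rep(beta, each = n)
  out <- aperm(array(y, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(out = out, mu = mu, va = va,
       cache = list(xhat = xhat, inv = inv, g = g, d = d, n = n))
}

bn_bwd <- function(cache, dout) {
  d <- cache$d; n <- cache$n
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  xhat <- cache$xhat
  dg <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(cache$g, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx_m <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
    rep(cache$inv, each = n)
  dx <- aperm(array(dx_m, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, dg = dg, dbeta = dbeta)
}

bn_eval <- function(x, g, beta, rm, rv, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  n <- nrow(m)
  y <- (m - rep(rm, each = n)) * rep(g / sqrt(rv + eps), each = n) +
    rep(beta, each = n)
  aperm(array(y, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

# ---- linear / normalization -------------------------------------------

# x: (in, M); W: (out, in); b: (out) or NULL
linear_fwd <- function(x, W, b = NULL) {
  out <- W %*% x
  if (!is.null(b)) out <- out + b
  list(out = out, cache = list(x = x, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(cache, dout) {
  list(dx = crossprod(cache$W, dout),
       dW = tcrossprod(dout, cache$x),
       db = if (cache$has_b) rowSums(dout) else NULL)
}

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}
gelu_bwd <- function(cache, dout)
  dout * (cache$ph + cache$x * stats::dnorm(cache$x))

# LayerNorm over the first dimension of a (D, M) matrix.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  D <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = D)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = D)
  out <- xhat * g + b
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(cache, dout) {
  xhat <- cache$xhat
  D <- nrow(xhat)
  dg <- rowSums(dout * xhat)
  db <- rowSums(dout)
  dxhat <- dout * cache$g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = D) - xhat * rep(m2, each = D)) *
    rep(cache$inv, each = D)
  list(dx = dx, dg = dg, db = db)
}

softmax_cols <- function(x) {
  m <- apply(x, 2, max)
  e <- exp(sweep(x, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# d/dx of y = softmax_cols(x) given dy
softmax_cols_bwd <- function(y, dy) {
  s <- colSums(dy * y)
  y * sweep(dy, 2, s)
}

# ---- multi-head self-attention ----------------------------------------
# The q/k/v/output projections are batched over the whole token matrix
# (D, N1*B); only the attention core (scores, softmax, weighted sum) runs
# per image and head. Queries and keys are L2-normalized per head with a
# fixed temperature sqrt(dh) (QK normalization): attention logits stay in
# [-sqrt(dh), sqrt(dh)] no matter how large the projections grow, which
# removes the attention-sharpening divergence that plain dot-product
# attention exhibits under momentum SGD.

# column-wise L2 normalization with cached inverse norms
l2norm_cols <- function(M, eps = 1e-6) {
  inv <- 1 / sqrt(colSums(M * M) + eps)
  list(out = M * rep(inv, each = nrow(M)), inv = inv)
}

# backward of column-wise L2 normalization
l2norm_cols_bwd <- function(Mhat, inv, dMhat) {
  s <- colSums(dMhat * Mhat)
  (dMhat - Mhat * rep(s, each = nrow(Mhat))) * rep(inv, each = nrow(Mhat))
}

mha_fwd <- function(Xmat, p, heads, N1, B) {
  D <- nrow(Xmat); dh <- D %/% heads
  Q <- p$Wq %*% Xmat + p$bq
  K <- p$Wk %*% Xmat + p$bk
  V <- p$Wv %*% Xmat + p$bv
  Qh <- matrix(0, D, N1 * B); Kh <- Qh
  Qinv <- matrix(0, heads, N1 * B); Kinv <- Qinv
  for (h in seq_len(heads)) {
    r <- ((h - 1L) * dh + 1L):(h * dh)
    nq <- l2norm_cols(Q[r, , drop = FALSE])
    nk <- l2norm_cols(K[r, , drop = FALSE])
    Qh[r, ] <- nq$out; Kh[r, ] <- nk$out
    Qinv[h, ] <- nq$inv; Kinv[h, ] <- nk$inv
  }
  O <- matrix(0, D, N1 * B)
  A <- array(0, dim = c(N1, N1, heads, B))
  tau <- sqrt(dh)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * N1 + 1L):(b * N1)
    for (h in seq_len(heads)) {
      r <- ((h - 1L) * dh + 1L):(h * dh)
      S <- crossprod(Qh[r, cols, drop = FALSE],
                     Kh[r, cols, drop = FALSE]) * tau
      E <- exp(S - apply(S, 1, max))
      Ab <- E / rowSums(E)
      A[, , h, b] <- Ab
      O[r, cols] <- V[r, cols, drop = FALSE] %*% t(Ab)
    }
  }
  out <- p$Wo %*% O + p$bo
  list(out = out,
       cache = list(X = Xmat, Qh = Qh, Kh = Kh, Qinv = Qinv, Kinv = Kinv,
                    V = V, O = O, A = A,
                    p = p, heads = heads, dh = dh, N1 = N1, B = B))
}

mha_bwd <- function(cache, dout) {
  p <- cache$p; dh <- cache$dh; heads <- cache$heads
  N1 <- cache$N1; B <- cache$B
  dWo <- tcrossprod(dout, cache$O)
  dbo <- rowSums(dout)
  dO <- crossprod(p$Wo, dout)
  dQh <- matrix(0, nrow(cache$Qh), ncol(cache$Qh))
  dKh <- dQh; dV <- dQh
  tau <- sqrt(dh)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * N1 + 1L):(b * N1)
    for (h in seq_len(heads)) {
      r <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[, , h, b]
      dOh <- dO[r, cols, drop = FALSE]
      dV[r, cols] <- dOh %*% A
      # dA[q,k] = sum_i dOh[i,q] * V[i,k]
      dA <- crossprod(dOh, cache$V[r, cols, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQh[r, cols] <- cache$Kh[r, cols, drop = FALSE] %*% t(dS) * tau
      dKh[r, cols] <- cache$Qh[r, cols, drop = FALSE] %*% dS * tau
    }
  }
  dQ <- dQh; dK <- dKh
  for (h in seq_len(heads)) {
    r <- ((h - 1L) * dh + 1L):(h * dh)
    dQ[r, ] <- l2norm_cols_bwd(cache$Qh[r, , drop = FALSE],
                               cache$Qinv[h, ], dQh[r, , drop = FALSE])
    dK[r, ] <- l2norm_cols_bwd(cache$Kh[r, , drop = FALSE],
                               cache$Kinv[h, ], dKh[r, , drop = FALSE])
  }
  dX <- crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) + crossprod(p$Wv, dV)
  list(dx = dX,
       grads = list(Wq = tcrossprod(dQ, cache$X), bq = rowSums(dQ),
                    Wk = tcrossprod(dK, cache$X), bk = rowSums(dK),
                    Wv = tcrossprod(dV, cache$X), bv = rowSums(dV),
                    Wo = dWo, bo = dbo))
}
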