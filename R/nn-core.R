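#' @title Low-level tensor operations for the network layers
#'
#' @description
#' Tensors are plain numeric arrays in `(C, H, W, N)` layout (channel first,
#' sample last). Channel-first keeps the channel contraction of a convolution
#' on the fastest-varying array dimension, so every kernel offset reduces to a
#' single BLAS matrix product without any `aperm()` copy.
#'
#' Convolutions are computed as a sum over the `k x k` kernel offsets: for each
#' offset the relevant input slice is a `(C_in, L)` matrix (`L = Ho*Wo*N`) and
#' the offset's weight slab is a `(C_in, C_out)` matrix. The transposed
#' convolution is the exact adjoint of this map, which makes the
#' forward/backward pairs symmetric and easy to verify by finite differences.
#'
#' @name nn-core
#' @keywords internal
NULL

# zero-pad the two spatial dims of a (C,H,W,N) tensor
pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv_out_size <- function(n, kernel, stride, pad, dilation) {
  span <- (kernel - 1L) * dilation + 1L
  (n + 2L * pad - span) %/% stride + 1L
}

#' Dense 2-D convolution forward pass (channel-first layout)
#'
#' @param x input tensor `(C_in, H, W, N)`.
#' @param W weight array `(k, k, C_in, C_out)`.
#' @param b bias vector of length `C_out`, or `NULL`.
#' @param stride,pad,dilation integer convolution geometry.
#' @return tensor `(C_out, Ho, Wo, N)`.
#' @keywords internal
conv2d_forward <- function(x, W, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  k <- dim(W)[1]
  ci <- dim(W)[3]; co <- dim(W)[4]
  stopifnot(dim(x)[1] == ci)
  xp <- pad_spatial(x, pad)
  dp <- dim(xp)
  ho <- conv_out_size(dim(x)[2], k, stride, pad, dilation)
  wo <- conv_out_size(dim(x)[3], k, stride, pad, dilation)
  n <- dp[4]
  L <- ho * wo * n
  out <- matrix(0, co, L)
  for (i in seq_len(k)) {
    yi <- seq.int(1L + (i - 1L) * dilation, by = stride, length.out = ho)
    for (j in seq_len(k)) {
      xi <- seq.int(1L + (j - 1L) * dilation, by = stride, length.out = wo)
      Xij <- xp[, yi, xi, , drop = FALSE]
      dim(Xij) <- c(ci, L)
      Wij <- matrix(W[i, j, , ], ci, co)
      out <- out + crossprod(Wij, Xij)
    }
  }
  if (!is.null(b)) out <- out + b
  dim(out) <- c(co, ho, wo, n)
  out
}

#' Dense 2-D convolution backward pass
#'
#' @param dout upstream gradient `(C_out, Ho, Wo, N)`.
#' @param x the forward input.
#' @inheritParams conv2d_forward
#' @return list with `dx`, `dW`, `db`.
#' @keywords internal
conv2d_backward <- function(dout, x, W, stride = 1L, pad = 0L, dilation = 1L) {
  k <- dim(W)[1]
  ci <- dim(W)[3]; co <- dim(W)[4]
  xp <- pad_spatial(x, pad)
  dp <- dim(xp)
  dd <- dim(dout)
  ho <- dd[2]; wo <- dd[3]; n <- dd[4]
  L <- ho * wo * n
  G <- dout
  dim(G) <- c(co, L)
  db <- rowSums(G)
  dW <- array(0, dim(W))
  dxp <- array(0, dp)
  for (i in seq_len(k)) {
    yi <- seq.int(1L + (i - 1L) * dilation, by = stride, length.out = ho)
    for (j in seq_len(k)) {
      xi <- seq.int(1L + (j - 1L) * dilation, by = stride, length.out = wo)
      Xij <- xp[, yi, xi, , drop = FALSE]
      dim(Xij) <- c(ci, L)
      dW[i, j, , ] <- tcrossprod(Xij, G)
      dXij <- matrix(W[i, j, , ], ci, co) %*% G
      dim(dXij) <- c(ci, ho, wo, n)
      dxp[, yi, xi, ] <- dxp[, yi, xi, , drop = FALSE] + dXij
    }
  }
  pad_ <- pad
  dx <- if (pad_ > 0L) {
    dxp[, pad_ + seq_len(dim(x)[2]), pad_ + seq_len(dim(x)[3]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

#' Transposed 2-D convolution forward pass (adjoint of [conv2d_forward])
#'
#' Output spatial size is `(H - 1) * stride - 2 * pad + span` with
#' `span = (k - 1) * dilation + 1`, matching the usual deconvolution
#' arithmetic used by DCGAN generators.
#'
#' @param x input tensor `(C_in, H, W, N)`.
#' @param W weight array `(k, k, C_in, C_out)`.
#' @inheritParams conv2d_forward
#' @keywords internal
convT2d_forward <- function(x, W, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  k <- dim(W)[1]
  ci <- dim(W)[3]; co <- dim(W)[4]
  d <- dim(x)
  stopifnot(d[1] == ci)
  h <- d[2]; w <- d[3]; n <- d[4]
  span <- (k - 1L) * dilation + 1L
  hout <- (h - 1L) * stride - 2L * pad + span
  wout <- (w - 1L) * stride - 2L * pad + span
  yp <- array(0, c(co, hout + 2L * pad, wout + 2L * pad, n))
  L <- h * w * n
  xm <- x
  dim(xm) <- c(ci, L)
  for (i in seq_len(k)) {
    yi <- seq.int(1L + (i - 1L) * dilation, by = stride, length.out = h)
    for (j in seq_len(k)) {
      xi <- seq.int(1L + (j - 1L) * dilation, by = stride, length.out = w)
      contrib <- crossprod(matrix(W[i, j, , ], ci, co), xm)
      dim(contrib) <- c(co, h, w, n)
      yp[, yi, xi, ] <- yp[, yi, xi, , drop = FALSE] + contrib
    }
  }
  out <- if (pad > 0L) {
    yp[, pad + seq_len(hout), pad + seq_len(wout), , drop = FALSE]
  } else yp
  if (!is.null(b)) {
    dim(out) <- c(co, hout * wout * n)
    out <- out + b
    dim(out) <- c(co, hout, wout, n)
  }
  out
}

#' Transposed 2-D convolution backward pass
#' @keywords internal
convT2d_backward <- function(dout, x, W, stride = 1L, pad = 0L, dilation = 1L) {
  k <- dim(W)[1]
  ci <- dim(W)[3]; co <- dim(W)[4]
  d <- dim(x)
  h <- d[2]; w <- d[3]; n <- d[4]
  L <- h * w * n
  dyp <- pad_spatial(dout, pad)
  xm <- x
  dim(xm) <- c(ci, L)
  G <- dout
  dim(G) <- c(co, length(G) / co)
  db <- rowSums(G)
  dW <- array(0, dim(W))
  dxm <- matrix(0, ci, L)
  for (i in seq_len(k)) {
    yi <- seq.int(1L + (i - 1L) * dilation, by = stride, length.out = h)
    for (j in seq_len(k)) {
      xi <- seq.int(1L + (j - 1L) * dilation, by = stride, length.out = w)
      Dij <- dyp[, yi, xi, , drop = FALSE]
      dim(Dij) <- c(co, L)
      dW[i, j, , ] <- tcrossprod(xm, Dij)
      dxm <- dxm + matrix(W[i, j, , ], ci, co) %*% Dij
    }
  }
  dim(dxm) <- c(ci, h, w, n)
  list(dx = dxm, dW = dW, db = db)
}

# ---- elementwise activations ------------------------------------------------

act_forward <- function(x, kind, slope = 0.2) {
  switch(kind,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, slope * x),
    swish = x * stats::plogis(x),
    tanh = tanh(x),
    sigmoid = stats::plogis(x),
    identity = x,
    stop("unknown activation: ", kind)
  )
}

act_backward <- function(dout, x, kind, slope = 0.2) {
  g <- switch(kind,
    relu = (x > 0) + 0,
    lrelu = ifelse(x > 0, 1, slope),
    swish = {
      s <- stats::plogis(x)
      s * (1 + x * (1 - s))
    },
    tanh = 1 - tanh(x)^2,
    sigmoid = {
      s <- stats::plogis(x)
      s * (1 - s)
    },
    identity = 1,
    stop("unknown activation: ", kind)
  )
  dout * g
}

# global average pool (C,H,W,N) -> (C,N)
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  apply_mean <- colMeans(aperm(m, c(2, 1, 3)))  # (C, N)
  matrix(apply_mean, d[1], d[4])
}

gap_backward <- function(dout, xdim) {
  hw <- xdim[2] * xdim[3]
  full <- array(rep(as.vector(dout), each = hw), c(hw, xdim[1], xdim[4]))
  full <- aperm(full, c(2, 1, 3))
  dim(full) <- xdim
  full / hw
}

#' Numerically stable softmax over the first dimension of a (K, N) matrix
#' @keywords internal
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Cross-entropy loss with softmax gradient
#'
#' @param logits `(K, N)` matrix of pre-softmax scores.
#' @param y integer class labels in `1..K`, length `N`.
#' @return list with `loss`, `probs`, `dlogits`.
#' @keywords internal
softmax_xent <- function(logits, y) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(y, seq_len(n))
  pt <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(pt, 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, probs = p, dlogits = dl / n)
}

#' Binary cross-entropy on probabilities (clamped for stability)
#' @keywords internal
bce <- function(p, target) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(p, target) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  (-(target / p) + (1 - target) / (1 - p)) / length(p)
}
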