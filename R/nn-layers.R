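#' @title Trainable layers with hand-derived backpropagation
#'
#' @description
#' Each layer is a mutable environment holding its parameters, parameter
#' gradients and forward cache, with a uniform interface: `fw(x, train)`,
#' `bw(dout)` (returns the input gradient and fills the parameter gradients),
#' and `params()/grads()/set_params()` for the optimizer. Networks are ordered
#' lists of named layers; non-sequential wiring (context-block residual adds,
#' the fused atrous stack) is composed by the network-level forward/backward
#' functions in the classifier and GAN modules.
#'
#' @name nn-layers
#' @keywords internal
NULL

he_normal <- function(n, fan_in) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

#' Convolution layer (optionally transposed)
#' @keywords internal
layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 0L,
                       dilation = 1L, bias = TRUE, transposed = FALSE) {
  e <- new.env(parent = emptyenv())
  e$type <- if (transposed) "convT" else "conv"
  e$kernel <- kernel; e$stride <- stride; e$pad <- pad; e$dilation <- dilation
  fan_in <- kernel * kernel * in_ch
  e$W <- array(he_normal(kernel * kernel * in_ch * out_ch, fan_in),
               c(kernel, kernel, in_ch, out_ch))
  e$b <- if (bias) numeric(out_ch) else NULL
  e$fw <- function(x, train = TRUE) {
    e$x <- x
    if (transposed) convT2d_forward(x, e$W, e$b, stride, pad, dilation)
    else conv2d_forward(x, e$W, e$b, stride, pad, dilation)
  }
  e$bw <- function(dout) {
    g <- if (transposed) convT2d_backward(dout, e$x, e$W, stride, pad, dilation)
    else conv2d_backward(dout, e$x, e$W, stride, pad, dilation)
    e$dW <- g$dW
    if (!is.null(e$b)) e$db <- g$db
    g$dx
  }
  e$params <- function() {
    p <- list(W = e$W)
    if (!is.null(e$b)) p$b <- e$b
    p
  }
  e$grads <- function() {
    g <- list(W = e$dW)
    if (!is.null(e$b)) g$b <- e$db
    g
  }
  e$set_params <- function(p) {
    e$W[] <- p$W
    if (!is.null(e$b)) e$b[] <- p$b
  }
  class(e) <- "nn_layer"
  e
}

#' Fully connected layer on (features, batch) matrices
#' @keywords internal
layer_dense <- function(in_f, out_f, bias = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$W <- matrix(he_normal(out_f * in_f, in_f), out_f, in_f)
  e$b <- if (bias) numeric(out_f) else NULL
  e$fw <- function(x, train = TRUE) {
    e$x <- x
    y <- e$W %*% x
    if (!is.null(e$b)) y <- y + e$b
    y
  }
  e$bw <- function(dout) {
    e$dW <- tcrossprod(dout, e$x)
    if (!is.null(e$b)) e$db <- rowSums(dout)
    crossprod(e$W, dout)
  }
  e$params <- function() {
    p <- list(W = e$W)
    if (!is.null(e$b)) p$b <- e$b
    p
  }
  e$grads <- function() {
    g <- list(W = e$dW)
    if (!is.null(e$b)) g$b <- e$db
    g
  }
  e$set_params <- function(p) {
    e$W[] <- p$W
    if (!is.null(e$b)) e$b[] <- p$b
  }
  class(e) <- "nn_layer"
  e
}

#' Batch normalization over (H, W, N) per channel
#' @keywords internal
layer_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "batchnorm"
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$run_mean <- rep(0, C); e$run_var <- rep(1, C)
  e$fw <- function(x, train = TRUE) {
    d <- dim(x)
    m <- x; dim(m) <- c(C, length(m) / C)
    if (train) {
      mu <- rowMeans(m)
      xc <- m - mu
      v <- rowMeans(xc * xc)
      e$run_mean <- (1 - momentum) * e$run_mean + momentum * mu
      e$run_var <- (1 - momentum) * e$run_var + momentum * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
      xc <- m - mu
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    y <- e$gamma * xhat + e$beta
    e$cache <- list(xhat = xhat, inv = inv, dims = d, train = train)
    dim(y) <- d
    y
  }
  e$bw <- function(dout) {
    cc <- e$cache
    G <- dout; dim(G) <- c(C, length(G) / C)
    e$dgamma <- rowSums(G * cc$xhat)
    e$dbeta <- rowSums(G)
    if (cc$train) {
      dx <- (e$gamma * cc$inv) *
        (G - rowMeans(G) - cc$xhat * rowMeans(G * cc$xhat))
    } else {
      dx <- (e$gamma * cc$inv) * G
    }
    dim(dx) <- cc$dims
    dx
  }
  e$params <- function() list(gamma = e$gamma, beta = e$beta)
  e$grads <- function() list(gamma = e$dgamma, beta = e$dbeta)
  e$set_params <- function(p) {
    e$gamma[] <- p$gamma
    e$beta[] <- p$beta
  }
  class(e) <- "nn_layer"
  e
}

#' Instance normalization over (H, W) per (channel, sample)
#' @keywords internal
layer_instancenorm <- function(C, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "instancenorm"
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  # work in (HW, C*N) layout; instance statistics are used in both modes,
  # so evaluation is deterministic per sample
  e$fw <- function(x, train = TRUE) {
    d <- dim(x)
    hw <- d[2] * d[3]
    m <- x; dim(m) <- c(C, hw, d[4])
    m <- aperm(m, c(2, 1, 3))
    dim(m) <- c(hw, C * d[4])
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, "*")
    gcol <- rep(e$gamma, times = d[4])
    y <- sweep(xhat, 2, gcol, "*")
    y <- sweep(y, 2, rep(e$beta, times = d[4]), "+")
    e$cache <- list(xhat = xhat, inv = inv, dims = d, hw = hw)
    dim(y) <- c(hw, C, d[4])
    y <- aperm(y, c(2, 1, 3))
    dim(y) <- d
    y
  }
  e$bw <- function(dout) {
    cc <- e$cache
    d <- cc$dims
    hw <- cc$hw
    G <- dout; dim(G) <- c(C, hw, d[4])
    G <- aperm(G, c(2, 1, 3))
    dim(G) <- c(hw, C * d[4])
    gx <- G * cc$xhat
    e$dgamma <- rowSums(matrix(colSums(gx), C, d[4]))
    e$dbeta <- rowSums(matrix(colSums(G), C, d[4]))
    gcol <- rep(e$gamma, times = d[4])
    scale <- gcol * cc$inv
    dx <- sweep(G, 2, colMeans(G)) - sweep(cc$xhat, 2, colMeans(gx), "*")
    dx <- sweep(dx, 2, scale, "*")
    dim(dx) <- c(hw, C, d[4])
    dx <- aperm(dx, c(2, 1, 3))
    dim(dx) <- d
    dx
  }
  e$params <- function() list(gamma = e$gamma, beta = e$beta)
  e$grads <- function() list(gamma = e$dgamma, beta = e$dbeta)
  e$set_params <- function(p) {
    e$gamma[] <- p$gamma
    e$beta[] <- p$beta
  }
  class(e) <- "nn_layer"
  e
}

#' Elementwise activation layer
#' @keywords internal
layer_act <- function(kind, slope = 0.2) {
  e <- new.env(parent = emptyenv())
  e$type <- paste0("act_", kind)
  e$fw <- function(x, train = TRUE) {
    e$x <- x
    act_forward(x, kind, slope)
  }
  e$bw <- function(dout) act_backward(dout, e$x, kind, slope)
  e$params <- function() list()
  e$grads <- function() list()
  e$set_params <- function(p) invisible(NULL)
  class(e) <- "nn_layer"
  e
}

#' Inverted dropout layer
#' @keywords internal
layer_dropout <- function(p = 0.3) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"
  e$fw <- function(x, train = TRUE) {
    if (!train || p <= 0) {
      e$mask <- NULL
      return(x)
    }
    m <- array(stats::runif(length(x)) >= p, dim(x)) / (1 - p)
    e$mask <- m
    x * m
  }
  e$bw <- function(dout) {
    if (is.null(e$mask)) dout else dout * e$mask
  }
  e$params <- function() list()
  e$grads <- function() list()
  e$set_params <- function(p) invisible(NULL)
  class(e) <- "nn_layer"
  e
}

# ---- parameter plumbing for optimizers --------------------------------------

#' Flatten a network's parameters into one named list
#' @keywords internal
net_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    p <- layers[[nm]]$params()
    for (pn in names(p)) out[[paste(nm, pn, sep = ".")]] <- p[[pn]]
  }
  out
}

#' @keywords internal
net_grads <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    g <- layers[[nm]]$grads()
    for (pn in names(g)) out[[paste(nm, pn, sep = ".")]] <- g[[pn]]
  }
  out
}

#' @keywords internal
net_set_params <- function(layers, flat) {
  for (nm in names(layers)) {
    p <- layers[[nm]]$params()
    if (length(p) == 0) next
    for (pn in names(p)) p[[pn]] <- flat[[paste(nm, pn, sep = ".")]]
    layers[[nm]]$set_params(p)
  }
  invisible(layers)
}

#' Total number of trainable scalars in a layer list
#' @keywords internal
net_n_params <- function(layers) {
  sum(vapply(net_params(layers), length, integer(1)))
}
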