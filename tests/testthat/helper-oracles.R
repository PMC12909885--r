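# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain double loops only.

# naive dense/dilated 2-D convolution on a (C,H,W,N) tensor
naive_conv2d <- function(x, W, b, stride = 1, pad = 0, dilation = 1) {
  d <- dim(x); k <- dim(W)[1]; ci <- d[1]; co <- dim(W)[4]
  hp <- d[2] + 2 * pad; wp <- d[3] + 2 * pad
  xp <- array(0, c(ci, hp, wp, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  span <- (k - 1) * dilation + 1
  ho <- (hp - span) %/% stride + 1
  wo <- (wp - span) %/% stride + 1
  out <- array(0, c(co, ho, wo, d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(co)) {
    for (y in seq_len(ho)) for (xq in seq_len(wo)) {
      s <- if (is.null(b)) 0 else b[o]
      for (i in seq_len(k)) for (j in seq_len(k)) for (c in seq_len(ci)) {
        s <- s + W[i, j, c, o] *
          xp[c, (y - 1) * stride + 1 + (i - 1) * dilation,
             (xq - 1) * stride + 1 + (j - 1) * dilation, n]
      }
      out[o, y, xq, n] <- s
    }
  }
  out
}

# brute-force Harris response scan: per-pixel loops, reflect borders,
# Gaussian window accumulated explicitly
brute_harris <- function(gray, k = 0.04, sigma = 1, rel_thresh = 0.01) {
  h <- nrow(gray); w <- ncol(gray)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  px <- function(y, x) gray[refl(y, h), refl(x, w)]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  ky <- t(kx)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    sx <- 0; sy <- 0
    for (i in 1:3) for (j in 1:3) {
      v <- px(y + i - 2, x + j - 2)
      sx <- sx + kx[i, j] * v
      sy <- sy + ky[i, j] * v
    }
    gx[y, x] <- sx; gy[y, x] <- sy
  }
  rad <- max(1, ceiling(2 * sigma))
  ax <- seq(-rad, rad)
  gk <- outer(ax, ax, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  gk <- gk / sum(gk)
  wsum <- function(m, y, x) {
    s <- 0
    for (i in seq_along(ax)) for (j in seq_along(ax)) {
      s <- s + gk[i, j] * m[refl(y + ax[i], h), refl(x + ax[j], w)]
    }
    s
  }
  resp <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    sxx <- wsum(gx * gx, y, x)
    syy <- wsum(gy * gy, y, x)
    sxy <- wsum(gx * gy, y, x)
    resp[y, x] <- sxx * syy - sxy^2 - k * (sxx + syy)^2
  }
  mx <- max(resp)
  if (mx <= 0) return(data.frame(row = integer(), col = integer()))
  keep <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (resp[y, x] < rel_thresh * mx) next
    best <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > h || xx < 1 || xx > w) next
      nb <- resp[yy, xx]
      if (nb > resp[y, x] ||
            (nb == resp[y, x] && !(dy > 0 || (dy == 0 && dx > 0)))) {
        best <- FALSE
      }
    }
    keep[y, x] <- best
  }
  idx <- which(keep, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2])
}

# per-sample metric recount: one-vs-rest tallies with plain loops
brute_metrics <- function(y_true, y_pred, k) {
  out <- list()
  for (c in seq_len(k)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == c && y_pred[i] == c) tp <- tp + 1
      else if (y_true[i] != c && y_pred[i] == c) fp <- fp + 1
      else if (y_true[i] == c && y_pred[i] != c) fn <- fn + 1
      else tn <- tn + 1
    }
    div <- function(a, b) if (b == 0) 0 else a / b
    prec <- div(tp, tp + fp); rec <- div(tp, tp + fn)
    out[[c]] <- c(precision = 100 * prec, recall = 100 * rec,
                  specificity = 100 * div(tn, tn + fp),
                  f1 = 100 * div(2 * prec * rec, prec + rec),
                  iou = 100 * div(tp, tp + fp + fn))
  }
  out
}

# tiny in-memory labelled image set from the fixture generator
fixture_tensor <- function(n_classes, n_per_class, size, seed,
                           gray_mode = "paper") {
  spec <- fixture_spec(n_classes, n_per_class, size, seed = seed)
  n <- n_classes * n_per_class
  x <- array(0, c(1, size, size, n))
  y <- integer(n)
  i <- 0
  for (ci in seq_len(n_classes)) {
    for (ii in seq_len(n_per_class)) {
      i <- i + 1
      x[1, , , i] <- to_grayscale(render_fixture_image(ci, ii, spec),
                                  gray_mode)
      y[i] <- ci
    }
  }
  list(x = x, y = y)
}

# small unassigned manifest without touching disk
dry_manifest <- function(n_classes = 8, n_per_class = 10) {
  spec <- fixture_spec(n_classes, n_per_class, 16, seed = 1)
  generate_fixture_dataset(spec, file.path(tempdir(), "dryman"),
                           write_images = FALSE)
}

# count 8-connected components of a logical matrix (flood fill)
n_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      y <- (p - 1L) %% nrow(mask) + 1L
      x <- (p - 1L) %/% nrow(mask) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= nrow(mask) && xx >= 1 && xx <= ncol(mask)) {
          q <- (xx - 1L) * nrow(mask) + yy
          if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  cur
}

# manifest of n copies of one rendered fixture image, single class
tiny_image_manifest <- function(n = 8, size = 16, class = "brazil_nut") {
  dir <- file.path(tempdir(), paste0("tiny_", n, "_", size))
  cdir <- file.path(dir, class)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture_spec(1, 1, size, seed = 5, color_mode = "grayscale")
  img <- render_fixture_image(1, 1, spec)
  paths <- file.path(cdir, sprintf("img%03d.png", seq_len(n)))
  for (p in paths) png::writePNG(img, p)
  new_manifest(tibble::tibble(
    id = sprintf("i%03d", seq_len(n)), path = paths, class = class,
    split = "unassigned", provenance = "original",
    source_id = NA_character_), class)
}
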