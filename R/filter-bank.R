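#' @title Classical feature filter bank
#'
#' @description
#' The filtration stage converts each image to grayscale and derives four
#' renderings from it: Sobel gradient magnitude, Canny edges, a corner-
#' keypoint-featured (CKPF) rendering built from Harris keypoints, and a
#' kernel-isolated (high-boost) rendering. All renderings live in `[0, 1]`
#' and preserve the input dimensions.
#'
#' @name filter-bank
NULL

# 2-D correlation with reflect (edge-mirrored) border handling
convolve2_reflect <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  h <- nrow(m); w <- ncol(m)
  ry <- kh %/% 2; rx <- kw %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    yi <- reflect_index(seq_len(h) + (i - 1L - ry), h)
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      xi <- reflect_index(seq_len(w) + (j - 1L - rx), w)
      out <- out + k[i, j] * m[yi, xi]
    }
  }
  out
}

gaussian_kernel <- function(sigma = 1, radius = max(1L, ceiling(2 * sigma))) {
  ax <- seq.int(-radius, radius)
  k <- outer(ax, ax, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k / sum(k)
}

sobel_kx <- function() matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
sobel_ky <- function() t(sobel_kx())

#' Convert an RGB image to grayscale
#'
#' Two weighting modes are provided. `"paper"` applies a two-stage weighting:
#' each channel is first scaled by the classic luminance coefficients
#' (0.2989, 0.5870, 0.1140) and the results are then recombined with weights
#' (0.3, 0.59, 0.11), so pure white maps to 0.44854 rather than 1.
#' `"standard"` is the single-stage ITU-R BT.601 luminance. Modes must not be
#' mixed within one run.
#'
#' @param image `(H, W, 3)` array; values either in `[0, 1]` or 0--255
#'   (detected automatically). A 2-D matrix is passed through unchanged.
#' @param mode `"paper"` (default) or `"standard"`.
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
#' @examples
#' px <- array(c(1, 0, 0), c(1, 1, 3))
#' to_grayscale(px, "paper")  # 0.2989 * 0.3 = 0.08967
to_grayscale <- function(image, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  if (length(dim(image)) == 2) return(clamp01(image))
  stop_if_not(length(dim(image)) == 3 && dim(image)[3] == 3,
              "to_grayscale() expects a 3-channel image")
  if (max(image) > 1) image <- image / 255
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  out <- if (mode == "paper") {
    (0.2989 * r) * 0.3 + (0.5870 * g) * 0.59 + (0.1140 * b) * 0.11
  } else {
    0.299 * r + 0.587 * g + 0.114 * b
  }
  clamp01(out)
}

# shared Sobel gradients (correlation with the standard 3x3 kernels)
sobel_gradients <- function(gray) {
  list(gx = convolve2_reflect(gray, sobel_kx()),
       gy = convolve2_reflect(gray, sobel_ky()))
}

#' Sobel gradient magnitude
#'
#' Per-pixel `sqrt(Gx^2 + Gy^2)` with the standard 3x3 Sobel kernels and
#' reflect borders, rescaled to `[0, 1]`. The rescaling factor (the maximum
#' unscaled magnitude) is recorded in the `"scale"` attribute.
#'
#' @param gray `(H, W)` grayscale matrix.
#' @return `(H, W)` matrix in `[0, 1]` with attribute `scale`.
#' @export
sobel_magnitude <- function(gray) {
  stop_if_not(nrow(gray) >= 3 && ncol(gray) >= 3,
              "image must be at least 3x3")
  g <- sobel_gradients(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  sc <- max(mag)
  out <- if (sc > 0) mag / sc else mag
  attr(out, "scale") <- sc
  out
}

#' Canny edge detection
#'
#' Standard pipeline: Gaussian smoothing (sigma = 1), Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' two-threshold hysteresis linking. Thresholds are relative to the maximum
#' suppressed gradient magnitude.
#'
#' @param gray `(H, W)` grayscale matrix.
#' @param low_rel,high_rel hysteresis thresholds, `0 < low_rel < high_rel <= 1`.
#' @param sigma Gaussian smoothing width in pixels.
#' @return logical `(H, W)` edge map.
#' @export
canny_edges <- function(gray, low_rel = 0.1, high_rel = 0.3, sigma = 1) {
  stop_if_not(low_rel > 0 && low_rel < high_rel && high_rel <= 1,
              "need 0 < low_rel < high_rel <= 1")
  h <- nrow(gray); w <- ncol(gray)
  sm <- convolve2_reflect(gray, gaussian_kernel(sigma))
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, h, w))
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift_mat <- function(m, dy, dx) {
    out <- matrix(0, h, w)
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    ok_y <- ys >= 1 & ys <= h; ok_x <- xs >= 1 & xs <= w
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nms <- matrix(0, h, w)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- shift_mat(mag, o[1], o[2])
    n2 <- shift_mat(mag, -o[1], -o[2])
    keep <- sector == s & mag >= n1 & mag >= n2
    nms[keep] <- mag[keep]
  }
  mx <- max(nms)
  strong <- nms >= high_rel * mx & nms > 0
  weak <- nms >= low_rel * mx & nms > 0
  # hysteresis: grow strong through weak until fixed point (8-connectivity)
  edge <- strong
  repeat {
    grown <- edge
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | shift_mat(edge, dy, dx)
    }
    grown <- grown & weak
    if (identical(grown, edge)) break
    edge <- grown
  }
  edge
}

#' Harris corner keypoints
#'
#' Harris response `R = det(M) - k * trace(M)^2` on the Gaussian-windowed
#' structure tensor of the Sobel gradients, thresholded at
#' `rel_thresh * max(R)` and reduced by 3x3 non-maximum suppression.
#'
#' @param gray `(H, W)` grayscale matrix.
#' @param k Harris sensitivity (default 0.04).
#' @param sigma Gaussian window width for the structure tensor.
#' @param rel_thresh response threshold relative to the maximum response.
#' @return a tibble of keypoints (`row`, `col`, `response`), strongest first,
#'   with the detector parameters attached as attribute `params`.
#' @export
detect_corners <- function(gray, k = 0.04, sigma = 1, rel_thresh = 0.01) {
  g <- sobel_gradients(gray)
  win <- gaussian_kernel(sigma)
  sxx <- convolve2_reflect(g$gx * g$gx, win)
  syy <- convolve2_reflect(g$gy * g$gy, win)
  sxy <- convolve2_reflect(g$gx * g$gy, win)
  resp <- harris_response(sxx, syy, sxy, k)
  kp <- select_corner_peaks(resp, rel_thresh)
  attr(kp, "params") <- list(k = k, sigma = sigma, rel_thresh = rel_thresh,
                             nms = "3x3")
  kp
}

harris_response <- function(sxx, syy, sxy, k) {
  sxx * syy - sxy^2 - k * (sxx + syy)^2
}

# threshold + 3x3 non-max suppression over a response surface
select_corner_peaks <- function(resp, rel_thresh) {
  h <- nrow(resp); w <- ncol(resp)
  mx <- max(resp)
  if (mx <= 0) {
    return(tibble(row = integer(), col = integer(), response = numeric()))
  }
  thr <- rel_thresh * mx
  is_peak <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- matrix(-Inf, h, w)
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    ok_y <- ys >= 1 & ys <= h; ok_x <- xs >= 1 & xs <= w
    nb[ok_y, ok_x] <- resp[ys[ok_y], xs[ok_x]]
    # strict dominance over later-ordered equal neighbours breaks plateaus
    is_peak <- is_peak & (resp > nb | (resp == nb & (dy > 0 | (dy == 0 & dx > 0))))
  }
  sel <- which(resp >= thr & is_peak, arr.ind = TRUE)
  out <- tibble(row = as.integer(sel[, 1]), col = as.integer(sel[, 2]),
                response = resp[sel])
  out[order(-out$response), ]
}

#' Corner-keypoint-featured (CKPF) rendering
#'
#' The grayscale image is attenuated by `alpha` everywhere; inside a disk of
#' radius `radius` around each keypoint the original intensity is restored
#' and boosted in proportion to the keypoint's normalized corner response.
#' With `alpha = 1, boost = 0` the rendering equals the input.
#'
#' @param gray `(H, W)` grayscale matrix.
#' @param keypoints tibble from [detect_corners()].
#' @param alpha background attenuation in `[0, 1]`.
#' @param radius disk radius in pixels.
#' @param boost maximum multiplicative response boost inside the disks.
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
render_ckpf <- function(gray, keypoints, alpha = 0.3, radius = 3, boost = 0.5) {
  out <- gray * alpha
  if (nrow(keypoints) == 0) return(clamp01(out))
  rmax <- max(keypoints$response)
  rnorm_ <- if (rmax > 0) keypoints$response / rmax else
    rep(1, nrow(keypoints))
  h <- nrow(gray); w <- ncol(gray)
  gain <- matrix(0, h, w)  # per-pixel restored gain, max over overlapping disks
  for (i in seq_len(nrow(keypoints))) {
    ys <- max(1, keypoints$row[i] - radius):min(h, keypoints$row[i] + radius)
    xs <- max(1, keypoints$col[i] - radius):min(w, keypoints$col[i] + radius)
    dy <- ys - keypoints$row[i]
    dx <- xs - keypoints$col[i]
    disk <- outer(dy^2, dx^2, "+") <= radius^2
    g <- (1 + boost * rnorm_[i]) * disk
    gain[ys, xs] <- pmax(gain[ys, xs], g)
  }
  restored <- gain > 0
  out[restored] <- gray[restored] * gain[restored]
  clamp01(out)
}

kernel_bank <- function() {
  list(
    identity = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, byrow = TRUE),
    laplacian_highboost = matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3,
                                 byrow = TRUE),
    sharpen = matrix(c(-1, -1, -1, -1, 9, -1, -1, -1, -1), 3, byrow = TRUE)
  )
}

#' Kernel-isolated rendering
#'
#' 3x3 convolution with a named high-boost kernel, reflect borders, clamped
#' to `[0, 1]`. Both named kernels have unit sum, so constant regions are
#' preserved and high-frequency structure is emphasized.
#'
#' @param gray `(H, W)` grayscale matrix.
#' @param kernel_name `"laplacian_highboost"`, `"sharpen"` or `"identity"`.
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
kernel_isolate <- function(gray, kernel_name = "laplacian_highboost") {
  bank <- kernel_bank()
  stop_if_not(kernel_name %in% names(bank), "unknown kernel: %s", kernel_name)
  clamp01(convolve2_reflect(gray, bank[[kernel_name]]))
}

#' Filtration configuration
#'
#' @param filters subset of `c("gray", "sobel", "canny", "ckpf", "kernel")`.
#' @param gray_mode grayscale weighting, `"paper"` or `"standard"`.
#' @param canny_low,canny_high relative hysteresis thresholds.
#' @param harris_k,harris_sigma,harris_rel_thresh corner detector parameters.
#' @param ckpf_alpha,ckpf_radius,ckpf_boost CKPF rendering parameters.
#' @param kernel_name kernel for the kernel-isolated rendering.
#' @return a `filter_config` list.
#' @export
filter_config <- function(filters = c("gray", "sobel", "canny", "ckpf", "kernel"),
                          gray_mode = "paper",
                          canny_low = 0.1, canny_high = 0.3,
                          harris_k = 0.04, harris_sigma = 1,
                          harris_rel_thresh = 0.01,
                          ckpf_alpha = 0.3, ckpf_radius = 3, ckpf_boost = 0.5,
                          kernel_name = "laplacian_highboost") {
  allowed <- c("gray", "sobel", "canny", "ckpf", "kernel")
  stop_if_not(all(filters %in% allowed), "unknown filter requested")
  structure(list(filters = filters, gray_mode = gray_mode,
                 canny_low = canny_low, canny_high = canny_high,
                 harris_k = harris_k, harris_sigma = harris_sigma,
                 harris_rel_thresh = harris_rel_thresh,
                 ckpf_alpha = ckpf_alpha, ckpf_radius = ckpf_radius,
                 ckpf_boost = ckpf_boost, kernel_name = kernel_name),
            class = "filter_config")
}

#' Run the whole filter bank on one image
#'
#' @param image RGB or grayscale image array.
#' @param config a [filter_config()].
#' @return list with `gray`, `sobel`, `canny`, `ckpf`, `kernel_isolated`
#'   renderings (those requested) and the `keypoints` tibble.
#' @export
filter_image <- function(image, config = filter_config()) {
  gray <- to_grayscale(image, config$gray_mode)
  out <- list(gray = gray)
  if ("sobel" %in% config$filters) out$sobel <- sobel_magnitude(gray)
  if ("canny" %in% config$filters) {
    out$canny <- canny_edges(gray, config$canny_low, config$canny_high)
  }
  kp <- NULL
  if ("ckpf" %in% config$filters) {
    kp <- detect_corners(gray, config$harris_k, config$harris_sigma,
                         config$harris_rel_thresh)
    out$ckpf <- render_ckpf(gray, kp, config$ckpf_alpha, config$ckpf_radius,
                            config$ckpf_boost)
  }
  if ("kernel" %in% config$filters) {
    out$kernel_isolated <- kernel_isolate(gray, config$kernel_name)
  }
  out$keypoints <- kp
  out
}

#' Write filter-bank renderings for every image in a manifest
#'
#' For each input record the requested renderings are written under
#' `out_dir/<filter>/<class>/` and appended to the manifest with
#' `provenance = "filtered"`; the split is inherited from the source image.
#' Per-file I/O failures are reported as warnings and the run continues.
#'
#' @param manifest input manifest (non-filtered records are processed).
#' @param config a [filter_config()].
#' @param out_dir output root.
#' @return the extended manifest.
#' @export
run_filtration <- function(manifest, config = filter_config(), out_dir) {
  stop_if_not(is_manifest(manifest), "not a manifest")
  src <- manifest[manifest$provenance != "filtered", ]
  rows <- purrr::map(seq_len(nrow(src)), function(i) {
    row <- src[i, ]
    res <- tryCatch({
      img <- read_image(row$path)
      fo <- filter_image(img, config)
      purrr::map(config$filters, function(tag) {
        ren <- switch(tag, gray = fo$gray, sobel = fo$sobel,
                      canny = fo$canny + 0, ckpf = fo$ckpf,
                      kernel = fo$kernel_isolated)
        cdir <- file.path(out_dir, tag, row$class)
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        p <- file.path(cdir, paste0(row$id, ".png"))
        png::writePNG(ren, p)
        tibble(id = paste0(row$id, "_f", tag), path = p, class = row$class,
               split = row$split, provenance = "filtered",
               source_id = row$id)
      }) %>% dplyr::bind_rows()
    }, error = function(e) {
      warning(sprintf("filtration failed for %s: %s", row$id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    res
  })
  new_manifest(dplyr::bind_rows(as_tibble(manifest), rows),
               class_names(manifest))
}
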