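#' Geometric image transforms: flips and rotations
#'
#' Images are numeric arrays in `[0, 1]`, either `(H, W)` grayscale or
#' `(H, W, C)`. The coordinate convention is 0-based origin at the top-left,
#' row-major, with positive rotation counter-clockwise on screen.
#'
#' `apply_flip()` reverses column order (horizontal) or row order (vertical),
#' preserving the pixel multiset exactly. `apply_rotation()` rotates about the
#' image centre; angles that are multiples of 90 degrees are applied as exact
#' pixel permutations, all other angles resample at the source size with
#' reflect padding and the requested interpolation.
#'
#' @param image numeric array, `(H, W)` or `(H, W, C)`.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return the transformed image, same shape (and same size for non-90
#'   rotations of square inputs).
#' @export
#' @examples
#' apply_flip(matrix(1:4, 2, byrow = TRUE), "horizontal")
apply_flip <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  stop_if_not(length(image) > 0, "empty image")
  per_channel(image, function(m) {
    if (axis == "horizontal") m[, ncol(m):1, drop = FALSE]
    else m[nrow(m):1, , drop = FALSE]
  })
}

per_channel <- function(image, f) {
  if (length(dim(image)) == 3) {
    out <- NULL
    for (ch in seq_len(dim(image)[3])) {
      r <- f(image[, , ch])
      if (is.null(out)) out <- array(0, c(dim(r), dim(image)[3]))
      out[, , ch] <- r
    }
    out
  } else {
    f(image)
  }
}

rot90_ccw <- function(m) t(m[, ncol(m):1, drop = FALSE])

# reflect an out-of-range 1-based index back into [1, n] (edge-mirrored)
reflect_index <- function(v, n) {
  if (n == 1) return(rep(1, length(v)))
  p <- (abs(v - 1)) %% (2 * n - 2)
  ifelse(p < n, p + 1, 2 * n - 1 - p)
}

#' @rdname apply_flip
#' @param angle_deg rotation angle in degrees, `[0, 360)`; positive is
#'   counter-clockwise.
#' @param interpolation `"bilinear"` or `"nearest"` (non-90 angles only).
#' @export
apply_rotation <- function(image, angle_deg,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  angle_deg <- angle_deg %% 360
  stop_if_not(length(image) > 0, "empty image")
  if (angle_deg == 0) return(image)
  if (angle_deg %% 90 == 0) {
    k <- as.integer(angle_deg / 90)
    return(per_channel(image, function(m) {
      for (i in seq_len(k)) m <- rot90_ccw(m)
      m
    }))
  }
  th <- angle_deg * pi / 180
  per_channel(image, function(m) {
    h <- nrow(m); w <- ncol(m)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    dr <- matrix(seq_len(h) - cy, h, w)
    dc <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    sr <- cy + cos(th) * dr + sin(th) * dc
    sc <- cx - sin(th) * dr + cos(th) * dc
    if (interpolation == "nearest") {
      ri <- reflect_index(round(sr), h)
      ci <- reflect_index(round(sc), w)
      out <- m[cbind(as.vector(ri), as.vector(ci))]
    } else {
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0; fc <- sc - c0
      r0i <- reflect_index(r0, h); r1i <- reflect_index(r0 + 1, h)
      c0i <- reflect_index(c0, w); c1i <- reflect_index(c0 + 1, w)
      out <- (1 - fr) * (1 - fc) * m[cbind(as.vector(r0i), as.vector(c0i))] +
        (1 - fr) * fc * m[cbind(as.vector(r0i), as.vector(c1i))] +
        fr * (1 - fc) * m[cbind(as.vector(r1i), as.vector(c0i))] +
        fr * fc * m[cbind(as.vector(r1i), as.vector(c1i))]
    }
    matrix(out, h, w)
  })
}

#' The canonical 21-transform augmentation policy
#'
#' Three transform families (plain rotation, horizontal-flip-then-rotate,
#' vertical-flip-then-rotate) times the seven rotation angles
#' 45, 90, ..., 315 degrees: 21 non-identity `(family, angle)` transform
#' specifications per source image.
#'
#' @return a tibble with columns `family` (`"rotate"`), `angle_deg` and
#'   `compose_with` (`NA`, `"hflip"` or `"vflip"`, applied before rotation).
#' @export
#' @examples
#' nrow(default_policy())
default_policy <- function() {
  angles <- seq(45, 315, by = 45)
  tidyr::expand_grid(
    compose_with = c(NA_character_, "hflip", "vflip"),
    angle_deg = angles
  ) %>%
    dplyr::mutate(family = "rotate", .before = 1) %>%
    dplyr::arrange(!is.na(.data$compose_with), .data$compose_with,
                   .data$angle_deg)
}

#' Apply one policy entry to an image
#'
#' @param image input image array.
#' @param family `"rotate"`, `"hflip"` or `"vflip"` (pure flips carry no angle).
#' @param angle_deg rotation angle for the rotate family.
#' @param compose_with optional flip (`"hflip"`/`"vflip"`) applied before the
#'   rotation.
#' @inheritParams apply_rotation
#' @export
apply_transform <- function(image, family, angle_deg = NA,
                            compose_with = NA,
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  switch(family,
    hflip = apply_flip(image, "horizontal"),
    vflip = apply_flip(image, "vertical"),
    rotate = {
      if (!is.na(compose_with)) {
        image <- apply_flip(image, if (compose_with == "hflip") "horizontal"
                            else "vertical")
      }
      apply_rotation(image, angle_deg, interpolation)
    },
    stop("unknown transform family: ", family)
  )
}

#' Augment the post-holdout pool, 21 variants per image
#'
#' Applies every policy entry to every pool image (unassigned originals) and
#' appends the results with `provenance = "augmented"` and `source_id` set.
#' Test images are never augmented. With `write_images = FALSE` only the
#' manifest rows are produced.
#'
#' @param manifest manifest after [holdout_test()].
#' @param policy transform tibble, normally [default_policy()]; must have 21
#'   rows when `strict = TRUE`.
#' @param out_dir directory for augmented PNGs.
#' @param write_images write pixels or only bookkeeping rows.
#' @param strict enforce the 21-row policy.
#' @inheritParams apply_rotation
#' @return the extended manifest.
#' @export
augment_pool <- function(manifest, policy = default_policy(), out_dir = NULL,
                         write_images = TRUE, strict = TRUE,
                         interpolation = "bilinear") {
  stop_if_not(is_manifest(manifest), "not a manifest")
  stop_if_not(all(manifest$split %in% c("unassigned", "test")),
              "augment_pool() must run before train_val_split()")
  if (strict) {
    stop_if_not(nrow(policy) == 21,
                "augmentation policy must have exactly 21 transforms (got %d)",
                nrow(policy))
  }
  pool <- manifest[manifest$split == "unassigned" &
                     manifest$provenance == "original", ]
  if (nrow(pool) == 0) return(manifest)
  if (write_images) {
    stop_if_not(!is.null(out_dir), "out_dir required when writing images")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tags <- sprintf("t%02d", seq_len(nrow(policy)))
  nt <- length(tags)
  root <- out_dir %||% dirname(dirname(pool$path[1]))
  src_id <- rep(pool$id, each = nt)
  cls <- rep(pool$class, each = nt)
  aug_ids <- paste0(src_id, "_", rep(tags, times = nrow(pool)))
  new_rows <- tibble(
    id = aug_ids,
    path = file.path(root, cls, paste0(aug_ids, ".png")),
    class = cls, split = "unassigned", provenance = "augmented",
    source_id = src_id
  )
  if (write_images) {
    for (d in unique(file.path(root, pool$class))) {
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
    }
    paths <- matrix(new_rows$path, nrow = nt)
    for (i in seq_len(nrow(pool))) {
      img <- read_image(pool$path[i])
      for (k in seq_len(nt)) {
        out <- apply_transform(img, policy$family[k], policy$angle_deg[k],
                               policy$compose_with[k], interpolation)
        png::writePNG(clamp01(out), paths[k, i])
      }
    }
  }
  new_manifest(dplyr::bind_rows(as_tibble(manifest), list(new_rows)),
               class_names(manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PNG image as a numeric array, dropping any alpha channel
#' @param path PNG file path.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  img
}
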