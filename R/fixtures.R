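#' Specification of a synthetic fixture dataset
#'
#' The fixture generator produces deterministic "nut-like" images: each class
#' is a fixed parametric shape/texture family (ellipse, ridged ellipse,
#' triangle, rectangle, speckled disc, annulus, crescent, striped ellipse)
#' with a class-specific hue, and per-image seeded jitter in position
#' (+-10%), scale (+-20%), orientation (+-15 deg) and brightness (+-0.1).
#' Class appearance is tied to the class index, not to the run, so fold
#' experiments are comparable across seeds; equal specs yield byte-identical
#' image sets.
#'
#' @param n_classes number of classes (>= 1).
#' @param n_per_class images per class (>= 0).
#' @param image_size pixels per side; a power of two >= 8.
#' @param seed integer seed driving all per-image jitter.
#' @param color_mode `"rgb"` or `"grayscale"`.
#' @return an object of class `fixture_spec`.
#' @export
#' @examples
#' spec <- fixture_spec(n_classes = 3, n_per_class = 2, image_size = 16, seed = 1)
fixture_spec <- function(n_classes = 8, n_per_class = 500, image_size = 64,
                         seed = 1, color_mode = c("rgb", "grayscale")) {
  color_mode <- match.arg(color_mode)
  stop_if_not(n_classes >= 1, "n_classes must be >= 1")
  stop_if_not(n_per_class >= 0, "n_per_class must be >= 0")
  stop_if_not(image_size >= 8 && bitwAnd(image_size, image_size - 1L) == 0,
              "image_size must be a power of two >= 8")
  structure(
    list(n_classes = as.integer(n_classes),
         n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size),
         seed = as.integer(seed),
         color_mode = color_mode),
    class = "fixture_spec"
  )
}

fixture_class_names <- function(n_classes) {
  base <- c("brazil_nut", "cashew", "chestnut", "peanut",
            "pecan", "pistachio", "macadamia", "walnut")
  if (n_classes <= length(base)) return(base[seq_len(n_classes)])
  c(base, sprintf("class_%02d", seq.int(length(base) + 1L, n_classes)))
}

# minimal hue -> rgb (s, v fixed by caller); h in [0,1)
hue_rgb <- function(h, s = 0.55, v = 1) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
    "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
    "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

#' Render one fixture image
#'
#' @param class_idx 1-based class index selecting the shape family.
#' @param image_idx 1-based image index within the class (drives jitter).
#' @param spec a [fixture_spec()].
#' @return numeric array `(H, W, 3)` for rgb mode or `(H, W)` for grayscale,
#'   values in `[0, 1]`.
#' @export
render_fixture_image <- function(class_idx, image_idx, spec) {
  n <- spec$image_size
  fam <- (class_idx - 1L) %% 8L + 1L
  with_seed(derive_seed(spec$seed, "fixture", class_idx, image_idx), {
    cx <- 0.5 + stats::runif(1, -0.1, 0.1)
    cy <- 0.5 + stats::runif(1, -0.1, 0.1)
    sc <- stats::runif(1, 0.8, 1.2)
    th <- stats::runif(1, -pi / 12, pi / 12)
    bright <- stats::runif(1, -0.1, 0.1)
    ax <- (seq_len(n) - 0.5) / n
    u0 <- outer(rep(1, n), ax) - cx        # column coordinate
    v0 <- outer(ax, rep(1, n)) - cy        # row coordinate
    u <- (cos(th) * u0 - sin(th) * v0) * 2 / sc
    v <- (sin(th) * u0 + cos(th) * v0) * 2 / sc
    r <- sqrt(u^2 + v^2)
    tex <- switch(fam,
      # 1: smooth ellipse
      1 * ((u / 0.85)^2 + (v / 0.55)^2 <= 1),
      { # 2: radially ridged ellipse
        m <- ((u / 0.8)^2 + (v / 0.62)^2 <= 1)
        m * (0.6 + 0.4 * sin(8 * atan2(v, u))^2)
      },
      { # 3: triangle
        halfw <- 0.78 * (v + 0.7) / 1.35
        1 * (v >= -0.7 & v <= 0.65 & abs(u) <= halfw)
      },
      # 4: rectangle
      1 * (abs(u) <= 0.72 & abs(v) <= 0.45),
      { # 5: speckled disc
        m <- 1 * (r <= 0.72)
        m * matrix(stats::runif(n * n, 0.35, 1), n, n)
      },
      # 6: annulus
      1 * (r <= 0.72 & r >= 0.38),
      # 7: crescent
      1 * (r <= 0.72 & ((u - 0.28)^2 + v^2 > 0.55^2)),
      { # 8: striped ellipse
        m <- ((u / 0.82)^2 + (v / 0.58)^2 <= 1)
        m * (0.55 + 0.45 * (sin(9 * u) > 0))
      }
    )
    base <- 0.08 + matrix(stats::runif(n * n, 0, 0.04), n, n)
    level <- clamp01(0.78 + bright)
    if (spec$color_mode == "grayscale") {
      clamp01(base + tex * level * 0.85)
    } else {
      col <- hue_rgb((fam - 1) / 8)
      img <- array(0, c(n, n, 3))
      for (ch in 1:3) img[, , ch] <- clamp01(base + tex * level * col[ch])
      img
    }
  })
}

#' Generate a synthetic fixture dataset on disk
#'
#' Writes `n_classes * n_per_class` PNG images, one subdirectory per class,
#' and returns the corresponding manifest (all rows `split = "unassigned"`,
#' `provenance = "original"`). With `write_images = FALSE` only the manifest
#' is produced (paths point at not-yet-written files), which makes the
#' partition arithmetic of the full-size dataset instant.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @param write_images write pixels (`TRUE`) or only the manifest (`FALSE`).
#' @return a [new_manifest()] tibble.
#' @export
#' @examples
#' spec <- fixture_spec(n_classes = 2, n_per_class = 3, image_size = 16, seed = 1)
#' man <- generate_fixture_dataset(spec, tempfile("fix"))
#' manifest_counts(man)
generate_fixture_dataset <- function(spec, out_dir, write_images = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  classes <- fixture_class_names(spec$n_classes)
  if (write_images) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stop_if_not(dir.exists(out_dir), "cannot create output directory %s", out_dir)
  }
  rows <- purrr::map(seq_along(classes), function(ci) {
    cls <- classes[ci]
    cdir <- file.path(out_dir, cls)
    if (write_images) dir.create(cdir, showWarnings = FALSE)
    if (spec$n_per_class == 0) {
      return(tibble(id = character(), path = character(), class = character(),
                    split = character(), provenance = character(),
                    source_id = character()))
    }
    ids <- sprintf("%s_%04d", cls, seq_len(spec$n_per_class))
    paths <- file.path(cdir, paste0(ids, ".png"))
    if (write_images) {
      for (ii in seq_len(spec$n_per_class)) {
        png::writePNG(render_fixture_image(ci, ii, spec), paths[ii])
      }
    }
    tibble(id = ids, path = paths, class = cls,
           split = "unassigned", provenance = "original",
           source_id = NA_character_)
  })
  new_manifest(dplyr::bind_rows(rows), classes)
}

#' Hand-checkable toy matrices for the filter-bank oracles
#'
#' @param kind `"constant"` (all 0.5), `"step_edge"` (right third 1, rest 0),
#'   `"square"` (centred odd-sided block of ones) or `"l_shape"` (an
#'   L-shaped region with six geometric corners).
#' @param size matrix side, at most 9 (at least 5 for `"l_shape"`).
#' @return a numeric `size x size` matrix with values in \{0, 0.5, 1\}.
#' @export
#' @examples
#' make_toy_matrix("square", 7)
make_toy_matrix <- function(kind = c("constant", "step_edge", "square", "l_shape"),
                            size = 9) {
  kind <- match.arg(kind)
  stop_if_not(size <= 9 && size >= 3, "toy matrices are at most 9x9")
  m <- matrix(0, size, size)
  switch(kind,
    constant = matrix(0.5, size, size),
    step_edge = {
      m[, seq.int(floor(2 * size / 3) + 1L, size)] <- 1
      m
    },
    square = {
      side <- max(1L, 2L * (size %/% 4L) + 1L)
      lo <- (size - side) %/% 2L + 1L
      m[lo:(lo + side - 1L), lo:(lo + side - 1L)] <- 1
      m
    },
    l_shape = {
      stop_if_not(size >= 5, "l_shape needs size >= 5")
      # vertical bar plus horizontal foot, six corners
      m[2:(size - 1), 2:3] <- 1
      m[(size - 2):(size - 1), 2:(size - 1)] <- 1
      m
    }
  )
}
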