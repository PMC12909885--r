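test_that("grayscale conversion matches the hand-evaluated weightings", {
  white <- array(1, c(2, 2, 3))
  expect_equal(to_grayscale(white, "paper")[1, 1],
               0.2989 * 0.3 + 0.5870 * 0.59 + 0.1140 * 0.11)
  expect_equal(to_grayscale(white, "paper")[1, 1], 0.44854)
  expect_equal(to_grayscale(white, "standard")[1, 1], 1)
  black <- array(0, c(2, 2, 3))
  expect_equal(to_grayscale(black, "paper"), matrix(0, 2, 2))
  expect_equal(to_grayscale(black, "standard"), matrix(0, 2, 2))
  red <- array(rep(c(1, 0, 0), each = 4), c(2, 2, 3))
  expect_equal(to_grayscale(red, "paper")[1, 1], 0.08967)
  # 8-bit inputs are rescaled automatically
  red255 <- red * 255
  expect_equal(to_grayscale(red255, "paper"), to_grayscale(red, "paper"))
  expect_error(to_grayscale(array(1, c(2, 2, 4))), "3-channel")
})

test_that("sobel magnitude matches hand convolution and symmetries", {
  expect_equal(sobel_magnitude(matrix(0.5, 5, 5)),
               matrix(0, 5, 5), ignore_attr = TRUE)
  step <- make_toy_matrix("step_edge", 3)
  g <- nutnet:::sobel_gradients(step)
  expect_equal(abs(g$gx[2, 2]), 4)
  expect_equal(g$gy[2, 2], 0)
  set.seed(4)
  x <- matrix(runif(100), 10)
  m1 <- sobel_magnitude(x)
  m2 <- sobel_magnitude(apply_flip(x, "horizontal"))
  expect_equal(apply_flip(m1, "horizontal"), m2, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_error(sobel_magnitude(matrix(1, 2, 2)), "3x3")
})

test_that("canny finds one closed contour around a filled square", {
  expect_equal(sum(canny_edges(matrix(0.3, 10, 10))), 0)
  big <- matrix(0, 64, 64)
  big[23:42, 23:42] <- 1
  e <- canny_edges(big)
  expect_gt(sum(e), 0)
  expect_equal(n_components8(e), 1)
  # the contour encloses the square: edges near the boundary, none at centre
  expect_false(any(e[30:35, 30:35]))
})

test_that("raising canny thresholds never adds edge pixels", {
  set.seed(5)
  x <- matrix(runif(400), 20)
  x[5:15, 5:15] <- x[5:15, 5:15] + 2
  x <- x / max(x)
  lo <- canny_edges(x, 0.05, 0.2)
  hi <- canny_edges(x, 0.15, 0.45)
  expect_true(all(which(hi) %in% which(lo)))
  expect_error(canny_edges(x, 0.5, 0.3), "low_rel")
})

test_that("harris keypoints: flat images, square corners, L corners", {
  expect_equal(nrow(detect_corners(matrix(0.5, 16, 16))), 0)
  big <- matrix(0, 64, 64)
  big[23:42, 23:42] <- 1
  kp <- detect_corners(big)
  expect_equal(nrow(kp), 4)
  corners <- rbind(c(23, 23), c(23, 42), c(42, 23), c(42, 42))
  for (i in seq_len(4)) {
    d <- sqrt((kp$row - corners[i, 1])^2 + (kp$col - corners[i, 2])^2)
    expect_lte(min(d), 2)
  }
  # L-shaped region at a corner-resolvable scale: all six corners found
  L <- matrix(0, 32, 32)
  L[6:26, 6:14] <- 1
  L[18:26, 6:26] <- 1
  kl <- detect_corners(L)
  expect_equal(nrow(kl), 6)
  geo <- rbind(c(6, 6), c(6, 14), c(18, 15), c(18, 26), c(26, 26), c(26, 6))
  for (i in seq_len(6)) {
    d <- sqrt((kl$row - geo[i, 1])^2 + (kl$col - geo[i, 2])^2)
    expect_lte(min(d), 2)
  }
})

test_that("detector equals the brute-force response-scan oracle on all toys", {
  for (kind in c("constant", "step_edge", "square", "l_shape")) {
    for (size in c(5, 7, 9)) {
      m <- make_toy_matrix(kind, size)
      got <- detect_corners(m)
      want <- brute_harris(m)
      got_sorted <- got[order(got$row, got$col), c("row", "col")]
      want_sorted <- want[order(want$row, want$col), ]
      expect_equal(as.data.frame(got_sorted), as.data.frame(want_sorted),
                   ignore_attr = TRUE,
                   label = paste(kind, size))
    }
  }
})

test_that("corners rotate with the image", {
  sq <- matrix(0, 32, 32)
  sq[9:20, 7:26] <- 1  # asymmetric rectangle
  kp <- detect_corners(sq)
  kr <- detect_corners(apply_rotation(sq, 90))
  # (row, col) -> (n + 1 - col, row) under a 90-degree CCW permutation
  mapped <- data.frame(row = 32 + 1 - kp$col, col = kp$row)
  expect_equal(as.data.frame(kr[order(kr$row, kr$col), c("row", "col")]),
               mapped[order(mapped$row, mapped$col), ],
               ignore_attr = TRUE)
})

test_that("ckpf rendering attenuates background and boosts corners", {
  sq <- make_toy_matrix("square", 9)
  kp <- detect_corners(sq)
  none <- kp[0, ]
  expect_equal(render_ckpf(sq, none, alpha = 0.3), 0.3 * sq)
  expect_equal(render_ckpf(sq, kp, alpha = 1, boost = 0), sq)
  out <- render_ckpf(sq, kp, alpha = 0.3, radius = 2, boost = 0.5)
  expect_true(all(out >= 0 & out <= 1))
  # on a square large enough that the disks do not tile the whole shape,
  # corner disks end up brighter than the attenuated interior
  big <- matrix(0, 64, 64)
  big[23:42, 23:42] <- 1
  kb <- detect_corners(big)
  ob <- render_ckpf(big, kb, alpha = 0.3, radius = 3, boost = 0.5)
  disk <- matrix(FALSE, 64, 64)
  for (i in seq_len(nrow(kb))) {
    ys <- pmax(1, kb$row[i] - 3):pmin(64, kb$row[i] + 3)
    xs <- pmax(1, kb$col[i] - 3):pmin(64, kb$col[i] + 3)
    disk[ys, xs] <- TRUE
  }
  on_shape <- big > 0
  expect_gt(mean(ob[disk & on_shape]), mean(ob[!disk & on_shape]))
})

test_that("kernel isolation preserves constants and highlights edges", {
  expect_equal(kernel_isolate(matrix(0.4, 6, 6), "identity"),
               matrix(0.4, 6, 6))
  expect_equal(kernel_isolate(matrix(0.4, 6, 6), "laplacian_highboost"),
               matrix(0.4, 6, 6))
  # mid-contrast step so the high-boost response is not hidden by clamping
  step <- make_toy_matrix("step_edge", 9) * 0.4 + 0.3
  out <- kernel_isolate(step, "laplacian_highboost")
  edge_col <- floor(2 * 9 / 3) + 1L
  # response differs from the input only around the step
  expect_equal(out[, 1:(edge_col - 2)], step[, 1:(edge_col - 2)])
  expect_false(isTRUE(all.equal(out[, edge_col], step[, edge_col])))
  expect_false(isTRUE(all.equal(out[, edge_col - 1], step[, edge_col - 1])))
  expect_error(kernel_isolate(step, "emboss"), "unknown kernel")
})

test_that("renderings stay in range and share the source dimensions", {
  spec <- fixture_spec(3, 1, 32, seed = 6)
  img <- render_fixture_image(2, 1, spec)
  fo <- filter_image(img)
  for (nm in c("gray", "sobel", "ckpf", "kernel_isolated")) {
    expect_equal(dim(fo[[nm]]), c(32, 32), label = nm)
    expect_true(all(fo[[nm]] >= 0 & fo[[nm]] <= 1), label = nm)
  }
  expect_equal(dim(fo$canny), c(32, 32))
  expect_type(fo$canny[1], "logical")
  expect_s3_class(fo$keypoints, "tbl_df")
})

test_that("run_filtration writes the requested renderings deterministically", {
  spec <- fixture_spec(2, 2, 16, seed = 2)
  man <- generate_fixture_dataset(spec, withr::local_tempdir())
  out1 <- withr::local_tempdir()
  m1 <- run_filtration(man, filter_config(), out1)
  filt <- m1[m1$provenance == "filtered", ]
  expect_equal(nrow(filt), 5 * nrow(man))
  expect_true(all(file.exists(filt$path)))
  out2 <- withr::local_tempdir()
  m2 <- run_filtration(man, filter_config(), out2)
  f2 <- m2[m2$provenance == "filtered", ]
  expect_identical(unname(tools::md5sum(sort(filt$path))),
                   unname(tools::md5sum(sort(f2$path))))
  # CKPF-only mode: one rendering per image
  m3 <- run_filtration(man, filter_config(filters = "ckpf"),
                       withr::local_tempdir())
  expect_equal(sum(m3$provenance == "filtered"), nrow(man))
})
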