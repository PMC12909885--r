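test_that("context block adds the pooled image-level signal back", {
  spec <- classifier_spec(in_channels = 1, stem_channels = 4,
                          atrous_channels = 4, n_classes = 2)
  net <- nutnet:::with_seed(1, build_classifier(spec))
  # identity 1x1 kernel, zero bias: constant input c -> 2c after the block
  C <- 4
  net$layers$pre_ctx$set_params(list(W = diag(C), b = rep(0, C)))
  # push a channel-constant feature map through the block in isolation
  fm <- array(rep(c(0.1, 0.2, 0.3, 0.4), times = 8 * 8 * 2), c(C, 8, 8, 2))
  v <- net$layers$pre_ctx$fw(nutnet:::gap_forward(fm))
  out <- fm + nutnet:::gap_backward(v, dim(fm)) * (8 * 8)
  expect_equal(out[, 1, 1, 1], 2 * c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
  # zero input with zero bias stays zero
  zfm <- fm * 0
  vz <- net$layers$pre_ctx$fw(nutnet:::gap_forward(zfm))
  expect_equal(max(abs(vz)), 0)
})

test_that("global average pooling equals the brute-force summation", {
  set.seed(4)
  fm <- array(rnorm(3 * 5 * 7 * 2), c(3, 5, 7, 2))
  g <- nutnet:::gap_forward(fm)
  for (c in 1:3) for (n in 1:2) {
    s <- 0
    for (m in 1:5) for (w in 1:7) s <- s + fm[c, m, w, n]
    expect_equal(g[c, n], s / (5 * 7), tolerance = 1e-12)
  }
})

test_that("the dilated stack has receptive field 25 and preserves shape", {
  expect_equal(atrous_receptive_field(c(2, 4, 6)), 25L)
  expect_equal(atrous_receptive_field(c(1, 1, 1)), 7L)
  # functional check: the centre output of the rate-(2,4,6) stack depends on
  # pixels within radius 12 and not beyond
  convs <- nutnet:::with_seed(5, list(
    nutnet:::layer_conv(1, 1, 3, pad = 2, dilation = 2),
    nutnet:::layer_conv(1, 1, 3, pad = 4, dilation = 4),
    nutnet:::layer_conv(1, 1, 3, pad = 6, dilation = 6)
  ))
  run <- function(x) {
    for (l in convs) x <- l$fw(x)
    x
  }
  n <- 27; mid <- 14
  base <- array(0, c(1, n, n, 1))
  y0 <- run(base)[1, mid, mid, 1]
  inside <- base; inside[1, mid - 12, mid, 1] <- 1
  outside <- base; outside[1, mid - 13, mid, 1] <- 1
  expect_false(isTRUE(all.equal(run(inside)[1, mid, mid, 1], y0)))
  expect_equal(run(outside)[1, mid, mid, 1], y0)
  # same padding: spatial dims preserved for a range of sizes
  spec <- classifier_spec(stem_channels = 4, atrous_channels = 4,
                          n_classes = 2)
  net <- nutnet:::with_seed(1, build_classifier(spec))
  for (sz in c(8, 15, 32)) {
    x <- array(0.5, c(1, sz, sz, 1))
    r <- net$forward(x, capture = TRUE)
    expect_equal(dim(r$captured$atrous)[2:3], dim(r$captured$stem)[2:3])
  }
})

test_that("zero input with zero biases stays zero through the atrous stack", {
  convs <- nutnet:::with_seed(6, list(
    nutnet:::layer_conv(1, 2, 3, pad = 2, dilation = 2),
    nutnet:::layer_conv(2, 2, 3, pad = 4, dilation = 4)
  ))
  for (l in convs) l$b[] <- 0
  x <- array(0, c(1, 10, 10, 1))
  act <- nutnet:::layer_act("swish")
  y <- act$fw(convs[[2]]$fw(act$fw(convs[[1]]$fw(x))))
  expect_equal(max(abs(y)), 0)
})

test_that("classifier probabilities are normalized and uniform at zero head", {
  spec <- classifier_spec(stem_channels = 4, atrous_channels = 8,
                          n_classes = 8)
  net <- nutnet:::with_seed(3, build_classifier(spec))
  x <- nutnet:::with_seed(4, array(runif(1 * 16 * 16 * 5), c(1, 16, 16, 5)))
  r <- classifier_forward(x, net)
  expect_equal(colSums(r$probs), rep(1, 5), tolerance = 1e-6)
  net$layers$head$set_params(list(W = matrix(0, 8, 8), b = rep(0, 8)))
  r0 <- classifier_forward(x, net)
  expect_equal(as.vector(r0$probs), rep(0.125, 40), tolerance = 1e-12)
})

test_that("parameter counts follow the closed-form layer arithmetic", {
  ly <- nutnet:::with_seed(1, nutnet:::layer_conv(1, 8, 3))
  expect_equal(nutnet:::net_n_params(list(l = ly)), (3 * 3 * 1 + 1) * 8)
  base <- classifier_spec(stem_channels = 8, atrous_channels = 16,
                          n_classes = 8)
  wide <- classifier_spec(stem_channels = 8, atrous_channels = 32,
                          n_classes = 8)
  expect_gt(count_parameters(wide), 2 * count_parameters(base))
  # toggling context blocks changes the count by exactly C*C + C each
  off <- classifier_spec(stem_channels = 8, atrous_channels = 16,
                         n_classes = 8, use_pre_context = FALSE,
                         use_post_context = FALSE)
  pre_only <- classifier_spec(stem_channels = 8, atrous_channels = 16,
                              n_classes = 8, use_post_context = FALSE)
  expect_equal(count_parameters(pre_only) - count_parameters(off), 8 * 8 + 8)
  expect_equal(count_parameters(base) - count_parameters(pre_only),
               16 * 16 + 16)
})

test_that("every parameter receives gradient on a toy batch", {
  spec <- classifier_spec(stem_channels = 4, atrous_channels = 6,
                          n_classes = 3, dropout = 0)
  net <- nutnet:::with_seed(8, build_classifier(spec))
  x <- nutnet:::with_seed(9, array(runif(1 * 16 * 16 * 6), c(1, 16, 16, 6)))
  y <- rep(1:3, 2)
  fw <- net$forward(x, train = TRUE)
  sx <- nutnet:::softmax_xent(fw$logits, y)
  net$backward(sx$dlogits)
  norms <- vapply(nutnet:::net_grads(net$layers),
                  function(g) sqrt(sum(g^2)), numeric(1))
  expect_true(all(norms > 0))
})

test_that("whole-network gradients match finite differences", {
  spec <- classifier_spec(stem_channels = 2, atrous_channels = 3,
                          dilation_rates = c(2, 4, 6), n_classes = 2,
                          dropout = 0)
  net <- nutnet:::with_seed(10, build_classifier(spec))
  x <- nutnet:::with_seed(11, array(runif(1 * 14 * 14 * 2), c(1, 14, 14, 2)))
  y <- c(1, 2)
  loss_at <- function(flat) {
    nutnet:::net_set_params(net$layers, flat)
    nutnet:::softmax_xent(net$forward(x, train = TRUE)$logits, y)$loss
  }
  p <- nutnet:::net_params(net$layers)
  fw <- net$forward(x, train = TRUE)
  sx <- nutnet:::softmax_xent(fw$logits, y)
  net$backward(sx$dlogits)
  g <- nutnet:::net_grads(net$layers)
  set.seed(12)
  for (nm in c("stem_conv.W", "pre_ctx.W", "at2.W", "proj.W", "post_ctx.b",
               "head.W")) {
    idx <- sample(length(p[[nm]]), min(4, length(p[[nm]])))
    for (i in idx) {
      eps <- 1e-5
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = paste(nm, i))
    }
  }
  nutnet:::net_set_params(net$layers, p)
})

test_that("parallel atrous mode fuses branches of the same input", {
  spec <- classifier_spec(stem_channels = 3, atrous_channels = 3,
                          n_classes = 2, atrous_mode = "parallel")
  net <- nutnet:::with_seed(13, build_classifier(spec))
  x <- array(runif(1 * 12 * 12 * 2), c(1, 12, 12, 2))
  r <- net$forward(x)
  expect_equal(colSums(r$probs), rep(1, 2), tolerance = 1e-6)
})

test_that("training is deterministic, resumable and can early-stop", {
  dat <- fixture_tensor(3, 6, 16, seed = 21)
  spec <- classifier_spec(stem_channels = 4, atrous_channels = 8,
                          n_classes = 3)
  f1 <- fit_classifier(dat$x, dat$y, spec, epochs = 3, batch_size = 6,
                       lr = 1e-3, seed = 5)
  f2 <- fit_classifier(dat$x, dat$y, spec, epochs = 3, batch_size = 6,
                       lr = 1e-3, seed = 5)
  expect_equal(f1$history, f2$history)
  f0 <- fit_classifier(dat$x, dat$y, spec, epochs = 0, batch_size = 6,
                       seed = 5)
  ref <- nutnet:::with_seed(derive_seed(5, "clf-init"),
                            build_classifier(spec))
  expect_equal(nutnet:::net_params(f0$net$layers), nutnet:::net_params(ref$layers))
  pred <- predict(f1, dat$x)
  expect_length(pred, length(dat$y))
  expect_true(all(pred %in% f1$class_levels))
})

test_that("feature-map export honours stages, shapes and determinism", {
  dat <- fixture_tensor(2, 2, 16, seed = 30)
  spec <- classifier_spec(stem_channels = 4, atrous_channels = 6,
                          n_classes = 2)
  fit <- fit_classifier(dat$x, dat$y, spec, epochs = 1, batch_size = 4,
                        seed = 2)
  out <- withr::local_tempdir()
  maps <- export_feature_maps(fit, dat$x[, , , 1, drop = FALSE],
                              out_dir = out)
  expect_named(maps, c("stem", "pre_context", "atrous", "post_context"))
  for (m in maps) {
    expect_equal(dim(m), c(8, 8))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_length(list.files(out, pattern = "^fmap_.*png$"), 4)
  maps2 <- export_feature_maps(fit, dat$x[, , , 1, drop = FALSE])
  expect_identical(maps, maps2)
  # constant input: constant stem response away from the padded border
  const <- array(0.5, c(1, 16, 16, 1))
  cm <- export_feature_maps(fit, const, stages = "stem")
  interior <- cm$stem[2:7, 2:7]
  expect_equal(max(interior) - min(interior), 0)
  expect_error(export_feature_maps(fit, const, stages = "bottleneck"),
               "unknown stage")
})
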