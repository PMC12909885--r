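small_gan_spec <- function(...) {
  gan_spec(image_size = 16, base_channels = 8, batch_size = 8, epochs = 1, ...)
}

test_that("latent sampling is seeded, shaped and standard normal", {
  spec <- small_gan_spec()
  z1 <- sample_latent(10, spec, seed = 3)
  z2 <- sample_latent(10, spec, seed = 3)
  expect_identical(z1, z2)
  expect_equal(dim(sample_latent(1, spec, 1)), c(1, 100))
  big <- sample_latent(10000, gan_spec(image_size = 16), seed = 5)
  expect_lt(abs(mean(big)), 0.05)
  expect_lt(abs(sd(big) - 1), 0.05)
  expect_error(sample_latent(0, spec, 1), "batch")
})

test_that("generator output respects the tanh range and spatial contract", {
  spec <- gan_spec(image_size = 32, base_channels = 8)
  gen <- nutnet:::with_seed(1, build_generator(spec))
  for (trial in 1:3) {
    z <- sample_latent(4, spec, seed = trial)
    out <- generator_forward(z, gen, train = FALSE)
    expect_equal(dim(out), c(1, 32, 32, 4))
    expect_true(all(out >= -1 & out <= 1))
  }
  z <- sample_latent(4, spec, seed = 9)
  o1 <- generator_forward(z, gen, train = FALSE)
  o2 <- generator_forward(z, gen, train = FALSE)
  expect_identical(o1, o2)
})

test_that("discriminator outputs probabilities and 4x4 penultimate features", {
  spec <- small_gan_spec()
  disc <- nutnet:::with_seed(2, build_discriminator(spec))
  x <- nutnet:::with_seed(3, array(runif(1 * 16 * 16 * 5) * 2 - 1,
                                   c(1, 16, 16, 5)))
  r <- discriminator_forward(x, disc)
  expect_length(r$p, 5)
  expect_true(all(r$p > 0 & r$p < 1))
  expect_equal(dim(r$feats)[2:3], c(4, 4))
})

test_that("range invariants hold across random weights and inputs", {
  spec <- small_gan_spec()
  for (trial in 1:10) {
    gen <- nutnet:::with_seed(trial, build_generator(spec))
    disc <- nutnet:::with_seed(trial + 100, build_discriminator(spec))
    z <- sample_latent(2, spec, seed = trial)
    img <- generator_forward(z, gen, train = FALSE)
    expect_true(all(img >= -1 & img <= 1))
    p <- discriminator_forward(img, disc)$p
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("gan_loss matches its closed forms", {
  l <- gan_loss(rep(0.5, 4), rep(0.5, 4), fm_weight = 0)
  expect_equal(l$loss_d, 2 * log(2), tolerance = 1e-12)
  expect_equal(l$loss_g, log(2), tolerance = 1e-12)
  eps <- 1e-4
  lp <- gan_loss(rep(1 - eps, 4), rep(eps, 4), fm_weight = 0)
  expect_lt(lp$loss_d, 3 * eps)
  f <- array(rnorm(8 * 2), c(2, 2, 2, 2))
  lf <- gan_loss(rep(0.5, 2), rep(0.5, 2), f, f, fm_weight = 1)
  expect_equal(lf$fm_term, 0)
  expect_error(gan_loss(numeric(0), numeric(0)), "empty")
})

test_that("one training step sends gradients into every trainable tensor", {
  man <- tiny_image_manifest(n = 8, size = 16)
  spec <- small_gan_spec()
  fit <- train_dcgan(man, "brazil_nut", spec, withr::local_tempdir(),
                     seed = 1, max_steps = 1, sample_grid = FALSE)
  for (nets in list(fit$gen, fit$disc)) {
    g <- nutnet:::net_grads(nets)
    norms <- vapply(g, function(v) sqrt(sum(v^2)), numeric(1))
    expect_true(all(norms > 0))
  }
})

test_that("zero steps leaves the checkpoint at its seeded initialization", {
  man <- tiny_image_manifest(n = 8, size = 16)
  spec <- small_gan_spec()
  fit <- train_dcgan(man, "brazil_nut", spec, withr::local_tempdir(),
                     seed = 4, max_steps = 0, sample_grid = FALSE)
  ref <- nutnet:::with_seed(derive_seed(4, "gan-init-g", "brazil_nut"),
                            build_generator(spec))
  expect_equal(readRDS(fit$checkpoint_path)$params_g,
               nutnet:::net_params(ref))
})

test_that("checkpoints reload to identical generated images", {
  man <- tiny_image_manifest(n = 8, size = 16)
  spec <- small_gan_spec()
  out <- withr::local_tempdir()
  fit <- train_dcgan(man, "brazil_nut", spec, out, seed = 2, max_steps = 2,
                     sample_grid = FALSE)
  g1 <- generate_labeled(fit$checkpoint_path, 3, seed = 8,
                         out_dir = file.path(out, "a"))
  g2 <- generate_labeled(fit$checkpoint_path, 3, seed = 8,
                         out_dir = file.path(out, "b"))
  expect_equal(nrow(g1), 3)
  expect_true(all(g1$class == "brazil_nut"))
  expect_true(all(g1$provenance == "gan"))
  expect_identical(unname(tools::md5sum(g1$path)),
                   unname(tools::md5sum(g2$path)))
  expect_equal(nrow(generate_labeled(fit$checkpoint_path, 0, 1,
                                     file.path(out, "c"))), 0)
  expect_error(generate_labeled(file.path(out, "nope.rds"), 1, 1, out),
               "missing checkpoint")
})

test_that("network parameter counts match the closed-form layer arithmetic", {
  spec <- small_gan_spec()
  # generator: dense 100 -> 16*16 (c0=16 at 4x4), convT 16->8, convT 8->1
  gen <- nutnet:::with_seed(1, build_generator(spec))
  c0 <- 8 * 2^(spec$n_stages - 1)
  expected_gen <- (100 * c0 * 16 + c0 * 16) + 2 * c0 +         # dense + bn
    (4 * 4 * c0 * 8 + 8) + 2 * 8 +                             # up1 + bn1
    (4 * 4 * 8 * 1 + 1)                                        # up2
  expect_equal(nutnet:::net_n_params(gen), expected_gen)
  disc <- nutnet:::with_seed(1, build_discriminator(spec))
  expected_disc <- (4 * 4 * 1 * 8 + 8) +                       # conv1
    (4 * 4 * 8 * 16 + 16) + 2 * 16 +                           # conv2 + bn2
    (16 * 16 * 1 + 1)                                          # dense head
  expect_equal(nutnet:::net_n_params(disc), expected_disc)
})
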