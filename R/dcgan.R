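#' DCGAN specification
#'
#' Hyperparameters for one per-class generator/discriminator pair. Defaults
#' follow the common DCGAN recipe with AdamW, per-network learning rates
#' (generator 1e-4, discriminator 5e-4), betas (0.5, 0.999), batch size 64
#' and binary cross-entropy plus a feature-matching penalty on the
#' discriminator's penultimate feature map.
#'
#' @param latent_dim latent dimension (standard-normal prior).
#' @param image_size output resolution; power of two >= 16. The number of
#'   up/down-sampling stages is `log2(image_size) - 2`.
#' @param channels image channels (1 grayscale, 3 rgb).
#' @param base_channels width of the first discriminator stage.
#' @param lr_generator,lr_discriminator AdamW learning rates.
#' @param betas AdamW beta pair.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param fm_weight weight of the feature-matching loss term.
#' @return a `gan_spec` list.
#' @export
gan_spec <- function(latent_dim = 100, image_size = 64, channels = 1,
                     base_channels = 64, lr_generator = 1e-4,
                     lr_discriminator = 5e-4, betas = c(0.5, 0.999),
                     batch_size = 64, epochs = 300, fm_weight = 1) {
  stop_if_not(image_size >= 16 && bitwAnd(image_size, image_size - 1L) == 0,
              "image_size must be a power of two >= 16")
  structure(list(latent_dim = as.integer(latent_dim),
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 base_channels = as.integer(base_channels),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 betas = betas, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), fm_weight = fm_weight,
                 n_stages = as.integer(log2(image_size) - 2)),
            class = "gan_spec")
}

#' Sample latent vectors from the standard-normal prior
#'
#' @param batch number of vectors.
#' @param spec a [gan_spec()].
#' @param seed integer seed (deterministic batches).
#' @return a `(batch, latent_dim)` matrix.
#' @export
sample_latent <- function(batch, spec, seed = 1) {
  stop_if_not(batch >= 1, "batch must be >= 1")
  with_seed(seed, matrix(stats::rnorm(batch * spec$latent_dim),
                         batch, spec$latent_dim))
}

# sequential net helpers -------------------------------------------------------

layer_reshape <- function(to_dim_fn) {
  e <- new.env(parent = emptyenv())
  e$type <- "reshape"
  e$fw <- function(x, train = TRUE) {
    e$from <- dim(x) %||% c(length(x))
    n <- if (is.matrix(x)) ncol(x) else dim(x)[length(dim(x))]
    dim(x) <- c(to_dim_fn(), n)
    x
  }
  e$bw <- function(dout) {
    dim(dout) <- e$from
    dout
  }
  e$params <- function() list()
  e$grads <- function() list()
  e$set_params <- function(p) invisible(NULL)
  class(e) <- "nn_layer"
  e
}

layer_flatten <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "flatten"
  e$fw <- function(x, train = TRUE) {
    e$from <- dim(x)
    n <- e$from[length(e$from)]
    dim(x) <- c(length(x) / n, n)
    x
  }
  e$bw <- function(dout) {
    dim(dout) <- e$from
    dout
  }
  e$params <- function() list()
  e$grads <- function() list()
  e$set_params <- function(p) invisible(NULL)
  class(e) <- "nn_layer"
  e
}

seq_forward <- function(layers, x, train = TRUE, capture = character()) {
  caps <- list()
  for (nm in names(layers)) {
    x <- layers[[nm]]$fw(x, train)
    if (nm %in% capture) caps[[nm]] <- x
  }
  list(out = x, captured = caps)
}

# extra_grads are added to the gradient at the *output* of the named layer
seq_backward <- function(layers, dout, extra_grads = list()) {
  nms <- names(layers)
  g <- dout
  for (i in rev(seq_along(layers))) {
    eg <- extra_grads[[nms[i]]]
    if (!is.null(eg)) g <- g + eg
    g <- layers[[nms[i]]]$bw(g)
  }
  g
}

#' Build generator layers for a [gan_spec()]
#'
#' Dense projection of the latent vector to a `4 x 4` map, then
#' `n_stages` transposed-convolution stages (kernel 4, stride 2, batch norm,
#' ReLU) halving the channel count, and a final tanh. Weights are He-normal.
#' @param spec a [gan_spec()].
#' @return named list of layers.
#' @export
build_generator <- function(spec) {
  c0 <- spec$base_channels * 2^(spec$n_stages - 1L)
  layers <- list(
    project = layer_dense(spec$latent_dim, c0 * 16L),
    reshape = layer_reshape(function() c(c0, 4L, 4L)),
    proj_bn = layer_batchnorm(c0),
    proj_act = layer_act("relu")
  )
  ch <- c0
  for (s in seq_len(spec$n_stages)) {
    last <- s == spec$n_stages
    out_ch <- if (last) spec$channels else ch %/% 2L
    layers[[paste0("up", s)]] <-
      layer_conv(ch, out_ch, kernel = 4L, stride = 2L, pad = 1L,
                 transposed = TRUE)
    if (!last) {
      layers[[paste0("bn", s)]] <- layer_batchnorm(out_ch)
      layers[[paste0("act", s)]] <- layer_act("relu")
    }
    ch <- out_ch
  }
  layers$out_act <- layer_act("tanh")
  layers
}

#' Build discriminator layers for a [gan_spec()]
#'
#' Strided convolutions (kernel 4, stride 2) with LeakyReLU(0.2) and batch
#' norm from the second stage on, down to a `4 x 4` penultimate feature map
#' (layer name `"feat"`, used for feature matching), then flatten, dense and
#' sigmoid.
#' @param spec a [gan_spec()].
#' @return named list of layers.
#' @export
build_discriminator <- function(spec) {
  layers <- list()
  ch <- spec$channels
  out_ch <- spec$base_channels
  for (s in seq_len(spec$n_stages)) {
    layers[[paste0("conv", s)]] <-
      layer_conv(ch, out_ch, kernel = 4L, stride = 2L, pad = 1L)
    if (s > 1) layers[[paste0("bn", s)]] <- layer_batchnorm(out_ch)
    nm_act <- if (s == spec$n_stages) "feat" else paste0("act", s)
    layers[[nm_act]] <- layer_act("lrelu")
    ch <- out_ch
    out_ch <- out_ch * 2L
  }
  layers$flat <- layer_flatten()
  layers$head <- layer_dense(ch * 16L, 1L)
  layers$sig <- layer_act("sigmoid")
  layers
}

#' Generator forward pass
#'
#' @param z `(batch, latent_dim)` latent matrix.
#' @param gen generator layers from [build_generator()].
#' @param train training mode flag (batch-norm statistics).
#' @return image tensor `(C, H, W, batch)` with values in `[-1, 1]`.
#' @export
generator_forward <- function(z, gen, train = FALSE) {
  seq_forward(gen, t(z), train)$out
}

#' Discriminator forward pass
#'
#' @param x image tensor `(C, H, W, batch)` scaled to `[-1, 1]`.
#' @param disc discriminator layers from [build_discriminator()].
#' @param train training mode flag.
#' @return list with `p` (probabilities in (0,1), length batch) and `feats`
#'   (the penultimate `4 x 4` feature map).
#' @export
discriminator_forward <- function(x, disc, train = FALSE) {
  r <- seq_forward(disc, x, train, capture = "feat")
  list(p = as.numeric(r$out), feats = r$captured$feat)
}

#' Adversarial losses with feature matching
#'
#' `loss_d = BCE(real -> 1) + BCE(fake -> 0)`;
#' `loss_g = BCE(fake -> 1) + fm_weight * ||mean(real_feats) - mean(fake_feats)||^2`,
#' means taken per feature element over the batch.
#'
#' @param real_scores,fake_scores discriminator probabilities.
#' @param real_feats,fake_feats penultimate feature tensors (last dim batch);
#'   may be `NULL` when `fm_weight = 0`.
#' @param fm_weight feature-matching weight.
#' @return list with `loss_d`, `loss_g`, `fm_term`.
#' @export
gan_loss <- function(real_scores, fake_scores, real_feats = NULL,
                     fake_feats = NULL, fm_weight = 0) {
  stop_if_not(length(real_scores) > 0 && length(fake_scores) > 0,
              "empty score batch")
  loss_d <- bce(real_scores, 1) + bce(fake_scores, 0)
  fm <- 0
  if (fm_weight > 0 && !is.null(real_feats)) {
    mr <- rowMeans(matrix(real_feats, ncol = dim(real_feats)[4]))
    mf <- rowMeans(matrix(fake_feats, ncol = dim(fake_feats)[4]))
    fm <- sum((mr - mf)^2)
  }
  list(loss_d = loss_d, loss_g = bce(fake_scores, 1) + fm_weight * fm,
       fm_term = fm)
}

#' Load images from a manifest subset into a `[-1, 1]` tensor
#' @keywords internal
load_image_tensor <- function(paths, channels = 1, gray_mode = "standard") {
  imgs <- purrr::map(paths, function(p) {
    img <- read_image(p)
    if (channels == 1) {
      as.matrix(to_grayscale(img, gray_mode))
    } else {
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      img
    }
  })
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  x <- array(0, c(channels, h, w, length(imgs)))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    if (channels == 1) x[1, , , i] <- im
    else for (ch in seq_len(channels)) x[ch, , , i] <- im[, , ch]
  }
  x * 2 - 1
}

#' Train one per-class DCGAN
#'
#' Alternating updates (one discriminator step on a combined real+fake batch,
#' one generator step) with AdamW, per-network learning rates, cosine
#' annealing over the scheduled steps and He-normal initialization. The
#' training pool for the class excludes test images by construction.
#'
#' @param manifest manifest after [holdout_test()].
#' @param class_label class to model.
#' @param spec a [gan_spec()].
#' @param out_dir directory for the checkpoint and sample grids.
#' @param seed integer seed (initialization, shuffling, latent draws).
#' @param max_steps optional cap on total optimizer steps (overrides epochs).
#' @param sample_grid write a fixed-seed sample grid PNG each epoch.
#' @return a `gan_fit` list: `checkpoint_path`, `history` tibble (per-step
#'   generator/discriminator losses), `spec`.
#' @export
train_dcgan <- function(manifest, class_label, spec, out_dir, seed = 1,
                        max_steps = NULL, sample_grid = TRUE) {
  stop_if_not(class_label %in% class_names(manifest),
              "class %s absent from manifest", class_label)
  rows <- manifest[manifest$class == class_label &
                     manifest$split != "test" &
                     manifest$provenance %in% c("original", "augmented"), ]
  stop_if_not(nrow(rows) >= spec$batch_size,
              "need at least batch_size (%d) images of class %s, got %d",
              spec$batch_size, class_label, nrow(rows))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- load_image_tensor(rows$path, spec$channels)
  n <- dim(x)[4]
  steps_per_epoch <- max(1L, n %/% spec$batch_size)
  total_steps <- if (is.null(max_steps)) spec$epochs * steps_per_epoch else
    max_steps
  gen <- with_seed(derive_seed(seed, "gan-init-g", class_label),
                   build_generator(spec))
  disc <- with_seed(derive_seed(seed, "gan-init-d", class_label),
                    build_discriminator(spec))
  opt_g <- optim_adamw(spec$lr_generator, spec$betas, t_max = total_steps)
  opt_d <- optim_adamw(spec$lr_discriminator, spec$betas, t_max = total_steps)
  hist <- list()
  step <- 0L
  epoch <- 0L
  fixed_z <- sample_latent(16, spec, derive_seed(seed, "grid", class_label))
  with_seed(derive_seed(seed, "gan-train", class_label), {
    while (step < total_steps) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      for (bi in seq_len(steps_per_epoch)) {
        if (step >= total_steps) break
        step <- step + 1L
        pos <- ((bi - 1L) * spec$batch_size + seq_len(spec$batch_size) - 1L) %% n + 1L
        idx <- ord[pos]
        real <- x[, , , idx, drop = FALSE]
        nb <- length(idx)
        # --- discriminator step on combined real+fake batch
        z <- matrix(stats::rnorm(nb * spec$latent_dim), nb)
        fake <- generator_forward(z, gen, train = TRUE)
        both <- array(0, c(dim(real)[1:3], 2L * nb))
        both[, , , seq_len(nb)] <- real
        both[, , , nb + seq_len(nb)] <- fake
        rd <- discriminator_forward(both, disc, train = TRUE)
        p_real <- rd$p[seq_len(nb)]
        p_fake <- rd$p[nb + seq_len(nb)]
        real_feats <- rd$feats[, , , seq_len(nb), drop = FALSE]
        losses <- gan_loss(p_real, p_fake, fm_weight = 0)
        dp <- c(bce_grad(p_real, 1), bce_grad(p_fake, 0))
        seq_backward(disc, matrix(dp, 1))
        opt_d$step(disc)
        # --- generator step through the updated discriminator
        z <- matrix(stats::rnorm(nb * spec$latent_dim), nb)
        fake <- generator_forward(z, gen, train = TRUE)
        fd <- discriminator_forward(fake, disc, train = TRUE)
        gl <- gan_loss(p_real, fd$p, real_feats, fd$feats, spec$fm_weight)
        extra <- list()
        if (spec$fm_weight > 0) {
          mr <- rowMeans(matrix(real_feats, ncol = nb))
          mf <- rowMeans(matrix(fd$feats, ncol = nb))
          gfeat <- array(rep(2 * spec$fm_weight * (mf - mr) / nb, nb),
                         dim(fd$feats))
          extra$feat <- gfeat
        }
        dx <- seq_backward(disc, matrix(bce_grad(fd$p, 1), 1), extra)
        seq_backward(gen, dx)
        opt_g$step(gen)
        hist[[step]] <- tibble(step = step, epoch = epoch,
                               loss_d = losses$loss_d, loss_g = gl$loss_g,
                               fm = gl$fm_term)
      }
      if (sample_grid) {
        write_sample_grid(gen, fixed_z, spec,
                          file.path(out_dir, sprintf("samples_epoch%03d.png",
                                                     epoch)))
      }
    }
  })
  ckpt <- list(spec = spec, class_label = class_label, seed = seed,
               epoch = epoch, steps = step,
               params_g = net_params(gen), params_d = net_params(disc))
  ckpt_path <- file.path(out_dir, paste0("dcgan_", class_label, ".rds"))
  saveRDS(ckpt, ckpt_path)
  jsonlite::write_json(list(class = class_label, seed = seed, epoch = epoch,
                            steps = step, latent_dim = spec$latent_dim,
                            image_size = spec$image_size),
                       sub("\\.rds$", ".json", ckpt_path), auto_unbox = TRUE)
  structure(list(checkpoint_path = ckpt_path,
                 history = dplyr::bind_rows(hist), spec = spec,
                 gen = gen, disc = disc),
            class = "gan_fit")
}

load_gan_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  gen <- with_seed(0, build_generator(ckpt$spec))
  disc <- with_seed(0, build_discriminator(ckpt$spec))
  net_set_params(gen, ckpt$params_g)
  net_set_params(disc, ckpt$params_d)
  list(ckpt = ckpt, gen = gen, disc = disc)
}

write_sample_grid <- function(gen, z, spec, path, ncol_grid = 4) {
  imgs <- generator_forward(z, gen, train = FALSE)
  n <- dim(imgs)[4]
  s <- spec$image_size
  nr <- ceiling(n / ncol_grid)
  grid <- matrix(0, nr * s, ncol_grid * s)
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% ncol_grid) * s
    c0 <- ((i - 1) %% ncol_grid) * s
    grid[r0 + seq_len(s), c0 + seq_len(s)] <- (imgs[1, , , i] + 1) / 2
  }
  png::writePNG(clamp01(grid), path)
  invisible(path)
}

#' Generate labelled synthetic images from a trained checkpoint
#'
#' @param checkpoint_path path to a checkpoint written by [train_dcgan()].
#' @param n number of images.
#' @param seed integer seed for the latent draws.
#' @param out_dir output directory.
#' @return a tibble of manifest rows (`provenance = "gan"`).
#' @export
generate_labeled <- function(checkpoint_path, n, seed = 1, out_dir) {
  stop_if_not(file.exists(checkpoint_path), "missing checkpoint: %s",
              checkpoint_path)
  lg <- load_gan_checkpoint(checkpoint_path)
  cls <- lg$ckpt$class_label
  if (n == 0) {
    return(tibble(id = character(), path = character(), class = character(),
                  split = character(), provenance = character(),
                  source_id = character()))
  }
  cdir <- file.path(out_dir, cls)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  z <- sample_latent(n, lg$ckpt$spec, seed)
  imgs <- generator_forward(z, lg$gen, train = FALSE)
  ids <- sprintf("gan_%s_%05d", cls, seq_len(n))
  paths <- file.path(cdir, paste0(ids, ".png"))
  for (i in seq_len(n)) {
    im <- (imgs[, , , i, drop = FALSE] + 1) / 2
    if (dim(imgs)[1] == 1) {
      png::writePNG(clamp01(matrix(im, dim(imgs)[2], dim(imgs)[3])), paths[i])
    } else {
      png::writePNG(clamp01(aperm(array(im, dim(imgs)[1:3]), c(2, 3, 1))),
                    paths[i])
    }
  }
  tibble(id = ids, path = paths, class = cls, split = "unassigned",
         provenance = "gan", source_id = NA_character_)
}
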