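#' Atrous-context classifier specification
#'
#' The classifier is: stem (3x3 convolution, stride 2, instance norm, ReLU)
#' -> optional pre-context block -> dilated 3x3 convolution stack at rates
#' (2, 4, 6) with element-wise fusion and a 1x1 projection -> optional
#' post-context block -> global average pooling -> dropout -> dense softmax
#' head. A context block adds the image-level signal back to the feature
#' map: global average pool, a 1x1 convolution *without* nonlinearity, and a
#' broadcast addition onto the input.
#'
#' @param in_channels input channels (1 for a single filter rendering, 4 for
#'   the stacked variant, 3 for rgb).
#' @param stem_channels stem width.
#' @param atrous_channels width of the dilated stack.
#' @param dilation_rates increasing dilation rates of the stack.
#' @param dropout dropout probability before the head.
#' @param weight_decay decoupled L2 coefficient for AdamW.
#' @param n_classes number of output classes.
#' @param use_pre_context,use_post_context context-block toggles (both off
#'   reproduces the plain atrous variant).
#' @param atrous_mode `"sequential"` (consecutive convolutions, stage outputs
#'   fused by addition) or `"parallel"` (independent branches on the same
#'   input, summed).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(in_channels = 1, stem_channels = 32,
                            atrous_channels = 64, dilation_rates = c(2, 4, 6),
                            dropout = 0.3, weight_decay = 1e-5, n_classes = 8,
                            use_pre_context = TRUE, use_post_context = TRUE,
                            atrous_mode = c("sequential", "parallel")) {
  atrous_mode <- match.arg(atrous_mode)
  stop_if_not(all(dilation_rates > 0), "dilation rates must be positive")
  stop_if_not(n_classes >= 2, "need at least two classes")
  structure(list(in_channels = as.integer(in_channels),
                 stem_channels = as.integer(stem_channels),
                 atrous_channels = as.integer(atrous_channels),
                 dilation_rates = as.integer(dilation_rates),
                 dropout = dropout, weight_decay = weight_decay,
                 n_classes = as.integer(n_classes),
                 use_pre_context = use_pre_context,
                 use_post_context = use_post_context,
                 atrous_mode = atrous_mode),
            class = "classifier_spec")
}

#' Receptive field of the sequential dilated stack
#'
#' For consecutive dilated convolutions the receptive field grows by
#' `d_i * (k - 1)` per layer: `1 + sum(d_i) * (k - 1)` pixels per side.
#'
#' @param dilation_rates dilation rates of the stack.
#' @param kernel kernel side length.
#' @return integer receptive field in pixels.
#' @export
#' @examples
#' atrous_receptive_field(c(2, 4, 6))  # 25
atrous_receptive_field <- function(dilation_rates, kernel = 3) {
  as.integer(1 + sum(dilation_rates) * (kernel - 1))
}

#' Build an atrous-context classifier network
#'
#' @param spec a [classifier_spec()].
#' @return an `atrous_net` environment with `$layers`, `$forward()` and
#'   `$backward()`.
#' @export
build_classifier <- function(spec) {
  cs <- spec$stem_channels
  ca <- spec$atrous_channels
  rates <- spec$dilation_rates
  layers <- list(
    stem_conv = layer_conv(spec$in_channels, cs, 3L, stride = 2L, pad = 1L),
    stem_norm = layer_instancenorm(cs),
    stem_act = layer_act("relu")
  )
  if (spec$use_pre_context) layers$pre_ctx <- layer_dense(cs, cs)
  in_ch <- cs
  for (i in seq_along(rates)) {
    layers[[paste0("at", i)]] <-
      layer_conv(in_ch, ca, 3L, pad = rates[i], dilation = rates[i])
    layers[[paste0("at", i, "_act")]] <- layer_act("swish")
    in_ch <- if (spec$atrous_mode == "sequential") ca else cs
  }
  layers$proj <- layer_conv(ca, ca, 1L)
  if (spec$use_post_context) layers$post_ctx <- layer_dense(ca, ca)
  layers$drop <- layer_dropout(spec$dropout)
  layers$head <- layer_dense(ca, spec$n_classes)

  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$layers <- layers

  spatial_sum <- function(x) gap_forward(x) * (dim(x)[2] * dim(x)[3])

  ctx_forward <- function(x, ctx_layer) {
    v <- ctx_layer$fw(gap_forward(x), train = TRUE)       # (C, N)
    hw <- dim(x)[2] * dim(x)[3]
    add <- gap_backward(v, dim(x)) * hw                   # broadcast v
    x + add
  }
  ctx_backward <- function(dy, ctx_layer, xdim) {
    dv <- spatial_sum(dy)
    dg <- ctx_layer$bw(dv)
    dy + gap_backward(dg, xdim)
  }

  net$forward <- function(x, train = FALSE, capture = FALSE) {
    L <- net$layers
    s <- L$stem_act$fw(L$stem_norm$fw(L$stem_conv$fw(x, train), train), train)
    caps <- if (capture) list(stem = s) else NULL
    p <- if (spec$use_pre_context) ctx_forward(s, L$pre_ctx) else s
    if (capture) caps$pre_context <- p
    net$dim_s <- dim(s)
    stage_in <- p
    stage_out <- vector("list", length(rates))
    for (i in seq_along(rates)) {
      a <- L[[paste0("at", i, "_act")]]$fw(
        L[[paste0("at", i)]]$fw(stage_in, train), train)
      stage_out[[i]] <- a
      if (spec$atrous_mode == "sequential") stage_in <- a
    }
    fused <- Reduce(`+`, stage_out)
    dm <- L$proj$fw(fused, train)
    if (capture) caps$atrous <- dm
    net$dim_dm <- dim(dm)
    q <- if (spec$use_post_context) ctx_forward(dm, L$post_ctx) else dm
    if (capture) caps$post_context <- q
    net$dim_q <- dim(q)
    g <- gap_forward(q)
    d <- L$drop$fw(g, train)
    logits <- L$head$fw(d, train)
    list(logits = logits, probs = softmax_cols(logits), captured = caps)
  }

  net$backward <- function(dlogits) {
    L <- net$layers
    dd <- L$head$bw(dlogits)
    dg <- L$drop$bw(dd)
    dq <- gap_backward(dg, net$dim_q)
    ddm <- if (spec$use_post_context) {
      ctx_backward(dq, L$post_ctx, net$dim_dm)
    } else dq
    dfused <- L$proj$bw(ddm)
    if (spec$atrous_mode == "sequential") {
      dcarry <- NULL
      for (i in rev(seq_along(rates))) {
        da <- if (is.null(dcarry)) dfused else dfused + dcarry
        dcarry <- L[[paste0("at", i)]]$bw(L[[paste0("at", i, "_act")]]$bw(da))
      }
      dp <- dcarry
    } else {
      dp <- Reduce(`+`, lapply(seq_along(rates), function(i) {
        L[[paste0("at", i)]]$bw(L[[paste0("at", i, "_act")]]$bw(dfused))
      }))
    }
    ds <- if (spec$use_pre_context) {
      ctx_backward(dp, L$pre_ctx, net$dim_s)
    } else dp
    L$stem_conv$bw(L$stem_norm$bw(L$stem_act$bw(ds)))
  }
  class(net) <- "atrous_net"
  net
}

#' Forward pass through a classifier network
#'
#' @param x image tensor `(C, H, W, N)` in `[0, 1]`.
#' @param net an `atrous_net` from [build_classifier()].
#' @param train training mode (dropout active).
#' @return list with `logits` and `probs` (`n_classes x N`; columns sum to 1).
#' @export
classifier_forward <- function(x, net, train = FALSE) {
  r <- net$forward(x, train)
  r[c("logits", "probs")]
}

#' Trainable parameter count of a classifier
#'
#' @param spec a [classifier_spec()].
#' @return integer count (independent of image size).
#' @export
count_parameters <- function(spec) {
  net <- with_seed(0, build_classifier(spec))
  as.integer(net_n_params(net$layers))
}

#' Fit the classifier on in-memory tensors
#'
#' Cross-entropy training with AdamW (decoupled weight decay, cosine-annealed
#' learning rate over all scheduled steps), He-normal initialization, seeded
#' shuffling and dropout; optionally early-stops once training accuracy
#' reaches `early_stop_acc`. The parameters of the best validation epoch
#' (training epoch when no validation set is given) are restored at the end.
#'
#' @param x training tensor `(C, H, W, N)`.
#' @param y integer labels `1..n_classes`.
#' @param spec a [classifier_spec()].
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param lr AdamW learning rate.
#' @param seed integer seed.
#' @param x_val,y_val optional validation tensors.
#' @param early_stop_acc optional training-accuracy stop threshold.
#' @param class_levels optional class names (length `n_classes`).
#' @return a `nut_classifier` fit: `net`, `spec`, `history` tibble,
#'   `best_epoch`, `class_levels`.
#' @export
fit_classifier <- function(x, y, spec, epochs = 10, batch_size = 32,
                           lr = 1e-4, seed = 1, x_val = NULL, y_val = NULL,
                           early_stop_acc = NULL, class_levels = NULL) {
  n <- dim(x)[4]
  stop_if_not(length(y) == n, "labels do not match tensor batch")
  stop_if_not(all(y >= 1 & y <= spec$n_classes), "labels out of range")
  net <- with_seed(derive_seed(seed, "clf-init"), build_classifier(spec))
  steps_per_epoch <- ceiling(n / batch_size)
  opt <- optim_adamw(lr, betas = c(0.9, 0.999),
                     weight_decay = spec$weight_decay,
                     t_max = epochs * steps_per_epoch)
  hist <- list()
  best <- list(metric = -Inf, params = net_params(net$layers), epoch = 0L)
  with_seed(derive_seed(seed, "clf-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0; tr_correct <- 0
      for (bi in seq_len(steps_per_epoch)) {
        idx <- ord[(((bi - 1L) * batch_size + 1L):min(bi * batch_size, n))]
        xb <- x[, , , idx, drop = FALSE]
        fw <- net$forward(xb, train = TRUE)
        sx <- softmax_xent(fw$logits, y[idx])
        net$backward(sx$dlogits)
        opt$step(net$layers)
        tr_loss <- tr_loss + sx$loss * length(idx)
        tr_correct <- tr_correct + sum(apply(sx$probs, 2, which.max) == y[idx])
      }
      row <- tibble(epoch = ep, train_loss = tr_loss / n,
                    train_acc = tr_correct / n,
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(x_val)) {
        ev <- evaluate_tensor(net, x_val, y_val)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
      }
      hist[[ep]] <- row
      metric <- if (!is.null(x_val)) row$val_acc else row$train_acc
      if (metric > best$metric) {
        best <- list(metric = metric, params = net_params(net$layers),
                     epoch = ep)
      }
      if (!is.null(early_stop_acc) && row$train_acc >= early_stop_acc) break
    }
  })
  net_set_params(net$layers, best$params)
  structure(list(net = net, spec = spec,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch,
                 class_levels = class_levels %||%
                   as.character(seq_len(spec$n_classes))),
            class = "nut_classifier")
}

evaluate_tensor <- function(net, x, y, batch_size = 64) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- net$forward(x[, , , idx, drop = FALSE], train = FALSE)
    sx <- softmax_xent(fw$logits, y[idx])
    loss <- loss + sx$loss * length(idx)
    correct <- correct + sum(apply(sx$probs, 2, which.max) == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict classes or probabilities for an image tensor
#'
#' @param object a `nut_classifier` fit.
#' @param x image tensor `(C, H, W, N)`.
#' @param type `"class"` (character labels) or `"prob"` (probability matrix,
#'   classes in rows).
#' @param ... unused.
#' @export
predict.nut_classifier <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  n <- dim(x)[4]
  probs <- matrix(0, object$spec$n_classes, n)
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    probs[, idx] <- object$net$forward(x[, , , idx, drop = FALSE],
                                       train = FALSE)$probs
  }
  if (type == "prob") return(probs)
  object$class_levels[apply(probs, 2, which.max)]
}

#' @export
print.nut_classifier <- function(x, ...) {
  cat("<nut_classifier>", x$spec$n_classes, "classes,",
      count_parameters(x$spec), "parameters\n")
  cat("  dilation rates:", paste(x$spec$dilation_rates, collapse = ", "),
      "| pre-context:", x$spec$use_pre_context,
      "| post-context:", x$spec$use_post_context, "\n")
  cat("  best epoch:", x$best_epoch, "\n")
  invisible(x)
}

#' Assemble a classifier input tensor from a manifest
#'
#' Selects the requested rendering for each source row: `"raw"` loads the
#' image itself (grayscale when the spec has one input channel); a filter tag
#' (`"gray"`, `"sobel"`, `"canny"`, `"ckpf"`, `"kernel"`) loads the written
#' rendering when [run_filtration()] has produced it, and computes it on the
#' fly otherwise; `"stacked"` stacks sobel, canny, ckpf and kernel as four
#' channels.
#'
#' @param manifest the manifest (used to locate filtered renderings).
#' @param rows the source rows (original/augmented/gan) to load.
#' @param input rendering selector.
#' @param config a [filter_config()] for on-the-fly computation.
#' @return tensor `(C, H, W, N)` in `[0, 1]`.
#' @export
load_classifier_input <- function(manifest, rows, input = "ckpf",
                                  config = filter_config()) {
  tags <- if (input == "stacked") c("sobel", "canny", "ckpf", "kernel") else
    input
  filt <- manifest[manifest$provenance == "filtered", ]
  one_rendering <- function(row, tag) {
    if (tag == "raw") {
      img <- read_image(row$path)
      return(to_grayscale(img, config$gray_mode))
    }
    fid <- paste0(row$id, "_f", tag)
    hit <- match(fid, filt$id)
    if (!is.na(hit) && file.exists(filt$path[hit])) {
      return(read_image(filt$path[hit]))
    }
    fo <- filter_image(read_image(row$path),
                       filter_config_subset(config, tag))
    switch(tag, gray = fo$gray, sobel = fo$sobel, canny = fo$canny + 0,
           ckpf = fo$ckpf, kernel = fo$kernel_isolated)
  }
  first <- one_rendering(rows[1, ], tags[1])
  x <- array(0, c(length(tags), nrow(first), ncol(first), nrow(rows)))
  for (i in seq_len(nrow(rows))) {
    for (ti in seq_along(tags)) {
      x[ti, , , i] <- one_rendering(rows[i, ], tags[ti])
    }
  }
  x
}

filter_config_subset <- function(config, tags) {
  config$filters <- intersect(c("gray", "sobel", "canny", "ckpf", "kernel"),
                              unique(c(tags)))
  config
}

#' Train the classifier from a manifest
#'
#' @param manifest manifest with train/val splits assigned.
#' @param spec a [classifier_spec()].
#' @param train_cfg list of training options: `epochs`, `batch_size`, `lr`,
#'   `seed`, `input` (rendering selector), `early_stop_acc`,
#'   `filter_config`.
#' @param out_dir directory for the checkpoint (`classifier.rds` + JSON
#'   sidecar); `NULL` skips writing.
#' @return a `nut_classifier` fit (with `$checkpoint_path` when written).
#' @export
train_classifier <- function(manifest, spec, train_cfg = list(),
                             out_dir = NULL) {
  cfg <- utils::modifyList(
    list(epochs = 10, batch_size = 32, lr = 1e-4, seed = 1, input = "ckpf",
         early_stop_acc = NULL, filter_config = filter_config()),
    train_cfg)
  stop_if_not(any(manifest$split == "train"), "manifest has no train split")
  src <- manifest[manifest$provenance != "filtered", ]
  classes <- class_names(manifest)
  tr <- src[src$split == "train", ]
  va <- src[src$split == "val", ]
  stop_if_not(all(table(factor(tr$class, classes)) > 0),
              "every class needs at least one training image")
  x_tr <- load_classifier_input(manifest, tr, cfg$input, cfg$filter_config)
  y_tr <- match(tr$class, classes)
  x_va <- NULL; y_va <- NULL
  if (nrow(va) > 0) {
    x_va <- load_classifier_input(manifest, va, cfg$input, cfg$filter_config)
    y_va <- match(va$class, classes)
  }
  fit <- fit_classifier(x_tr, y_tr, spec, epochs = cfg$epochs,
                        batch_size = cfg$batch_size, lr = cfg$lr,
                        seed = cfg$seed, x_val = x_va, y_val = y_va,
                        early_stop_acc = cfg$early_stop_acc,
                        class_levels = classes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- list(spec = spec, params = net_params(fit$net$layers),
                 class_levels = classes, history = fit$history,
                 input = cfg$input, seed = cfg$seed)
    fit$checkpoint_path <- file.path(out_dir, "classifier.rds")
    saveRDS(ckpt, fit$checkpoint_path)
    jsonlite::write_json(
      list(n_classes = spec$n_classes, input = cfg$input, seed = cfg$seed,
           best_epoch = fit$best_epoch,
           parameters = count_parameters(spec)),
      file.path(out_dir, "classifier.json"), auto_unbox = TRUE)
  }
  fit
}

#' Reload a classifier checkpoint written by [train_classifier()]
#' @param path path to `classifier.rds`.
#' @export
load_classifier_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  net <- with_seed(0, build_classifier(ckpt$spec))
  net_set_params(net$layers, ckpt$params)
  structure(list(net = net, spec = ckpt$spec, history = ckpt$history,
                 best_epoch = NA_integer_, class_levels = ckpt$class_levels),
            class = "nut_classifier")
}

#' Export channel-averaged feature maps for selected stages
#'
#' @param fit a `nut_classifier`.
#' @param image a single image array (as read by [read_image()]) already in
#'   the classifier's input rendering, or a `(C, H, W, 1)` tensor.
#' @param stages subset of `c("stem", "pre_context", "atrous", "post_context")`.
#' @param out_dir optional directory; when given, each map is written as PNG.
#' @return named list of min-max-normalized `(H, W)` matrices.
#' @export
export_feature_maps <- function(fit, image,
                                stages = c("stem", "pre_context", "atrous",
                                           "post_context"),
                                out_dir = NULL) {
  allowed <- c("stem", "pre_context", "atrous", "post_context")
  stop_if_not(all(stages %in% allowed), "unknown stage name")
  x <- if (length(dim(image)) == 4) image else {
    m <- if (length(dim(image)) == 3) to_grayscale(image, "standard") else image
    array(m, c(1, nrow(m), ncol(m), 1))
  }
  r <- fit$net$forward(x, train = FALSE, capture = TRUE)
  out <- purrr::map(stages, function(st) {
    fm <- r$captured[[st]]
    if (is.null(fm)) return(NULL)
    avg <- apply(fm[, , , 1, drop = FALSE], c(2, 3), mean)
    rng <- range(avg)
    if (diff(rng) > 0) (avg - rng[1]) / diff(rng) else avg * 0
  })
  names(out) <- stages
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (st in names(out)) {
      png::writePNG(out[[st]], file.path(out_dir, paste0("fmap_", st, ".png")))
    }
  }
  out
}
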