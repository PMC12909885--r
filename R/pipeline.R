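#' Pipeline configuration
#'
#' One nested list drives the whole run. Defaults reproduce the reference
#' partition recipe (20% stratified test hold-out, 21-fold augmentation,
#' 80/20 train/validation) at desk scale. A configuration can be loaded from
#' YAML with [read_pipeline_config()]; `${VAR}` references in string values
#' are interpolated from environment variables.
#'
#' @param output_root run directory.
#' @param seed global seed; each stage derives its own child seed from it.
#' @param fixture named list of [fixture_spec()] arguments.
#' @param split list with `test_fraction` and `train_fraction`.
#' @param augmentation list with `interpolation`; the policy is
#'   [default_policy()].
#' @param filter named list of [filter_config()] arguments.
#' @param gan list: `enabled`, `per_class` (generated images per class) and
#'   [gan_spec()] arguments.
#' @param classifier list: [classifier_spec()] arguments plus `epochs`,
#'   `batch_size`, `lr`, `input`, `early_stop_acc`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_root = tempfile("nutnet_run_"),
                            seed = 1,
                            fixture = list(),
                            split = list(),
                            augmentation = list(),
                            filter = list(),
                            gan = list(),
                            classifier = list()) {
  cfg <- list(
    output_root = output_root,
    seed = as.integer(seed),
    fixture = utils::modifyList(
      list(n_classes = 8, n_per_class = 500, image_size = 64,
           color_mode = "rgb"), fixture),
    split = utils::modifyList(
      list(test_fraction = 0.2, train_fraction = 0.8), split),
    augmentation = utils::modifyList(
      list(interpolation = "bilinear"), augmentation),
    filter = filter,
    gan = utils::modifyList(
      list(enabled = FALSE, per_class = 0, epochs = 1,
           image_size = NULL, base_channels = 16, batch_size = 32), gan),
    classifier = utils::modifyList(
      list(epochs = 3, batch_size = 32, lr = 1e-3, input = "ckpf",
           early_stop_acc = NULL, stem_channels = 16, atrous_channels = 32),
      classifier)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- interpolate_env(raw)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

interpolate_env <- function(x) {
  if (is.list(x)) return(lapply(x, interpolate_env))
  if (is.character(x)) {
    return(vapply(x, function(s) {
      while (grepl("\\$\\{[^}]+\\}", s)) {
        var <- sub(".*\\$\\{([^}]+)\\}.*", "\\1", s)
        s <- sub(sprintf("\\$\\{%s\\}", var), Sys.getenv(var), s)
      }
      s
    }, character(1), USE.NAMES = FALSE))
  }
  x
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param policy augmentation policy to check (default [default_policy()]).
#' @return a tibble of issues (`field`, `problem`); zero rows when valid.
#' @export
validate_config <- function(config, policy = default_policy()) {
  issues <- list()
  add <- function(field, problem) {
    issues[[length(issues) + 1]] <<- tibble(field = field, problem = problem)
  }
  tf <- config$split$test_fraction
  if (!is.numeric(tf) || tf < 0 || tf >= 1) {
    add("split.test_fraction", "must be in [0, 1)")
  }
  rf <- config$split$train_fraction
  if (!is.numeric(rf) || rf <= 0 || rf > 1) {
    add("split.train_fraction", "must be in (0, 1]")
  }
  sz <- config$fixture$image_size
  if (!is.numeric(sz) || sz < 8 || bitwAnd(as.integer(sz), as.integer(sz) - 1L) != 0) {
    add("fixture.image_size", "must be a power of two >= 8")
  }
  if (nrow(policy) != 21) {
    add("augmentation.policy", sprintf("policy has %d transforms, expected 21",
                                       nrow(policy)))
  }
  if (!config$classifier$input %in%
        c("raw", "gray", "sobel", "canny", "ckpf", "kernel", "stacked")) {
    add("classifier.input", "unknown input rendering")
  }
  if (isTRUE(config$gan$enabled) && config$gan$per_class < 0) {
    add("gan.per_class", "must be >= 0")
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    tibble(field = character(), problem = character())
}

#' Run the full pipeline
#'
#' Fixture generation -> stratified test hold-out -> 21-fold geometric
#' augmentation -> optional per-class DCGAN training and synthetic image
#' generation -> filtration -> train/validation split -> classifier training
#' -> evaluation on the held-out test split. Every stage logs its seed and
#' elapsed time; a summary JSON with all stage counts and final metrics is
#' written to the run directory. With `dry_run = TRUE` only manifest
#' bookkeeping is performed (no pixels, no training), which makes the
#' partition arithmetic of the full-size dataset near-instant.
#'
#' @param config a [pipeline_config()].
#' @param dry_run bookkeeping only.
#' @param manifest optional pre-built manifest of real data (skips the
#'   fixture stage).
#' @param quiet suppress progress messages.
#' @return a `nut_pipeline_run` list: `summary`, `manifest`, `fit` (unless
#'   dry run), `report`, `run_dir`.
#' @export
run_pipeline <- function(config, dry_run = FALSE, manifest = NULL,
                         quiet = FALSE) {
  issues <- validate_config(config)
  stop_if_not(nrow(issues) == 0, "invalid config: %s",
              paste(issues$field, issues$problem, collapse = "; "))
  run_dir <- config$output_root
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "pipeline.log")
  seed <- config$seed
  stage_log <- list()
  log_stage <- function(stage, t0, extra = "") {
    line <- sprintf("[%s] stage=%s seed=%d elapsed=%.2fs %s",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    derive_seed(seed, stage),
                    as.numeric(Sys.time()) - t0, extra)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }

  t0 <- as.numeric(Sys.time())
  if (is.null(manifest)) {
    fspec <- do.call(fixture_spec, c(config$fixture,
                                     list(seed = derive_seed(seed, "fixtures"))))
    manifest <- generate_fixture_dataset(fspec, file.path(run_dir, "images"),
                                         write_images = !dry_run)
  }
  log_stage("fixtures", t0, sprintf("images=%d", nrow(manifest)))

  t0 <- as.numeric(Sys.time())
  manifest <- holdout_test(manifest, config$split$test_fraction,
                           derive_seed(seed, "holdout"))
  s <- manifest_summary(manifest)
  log_stage("holdout", t0, sprintf("test=%d pool=%d", s$test, s$pool))

  t0 <- as.numeric(Sys.time())
  manifest <- augment_pool(manifest, default_policy(),
                           file.path(run_dir, "augmented"),
                           write_images = !dry_run,
                           interpolation = config$augmentation$interpolation)
  s <- manifest_summary(manifest)
  log_stage("augment", t0, sprintf("augmented=%d total=%d", s$augmented,
                                   s$total))

  gan_ckpts <- list()
  if (isTRUE(config$gan$enabled) && !dry_run) {
    t0 <- as.numeric(Sys.time())
    gargs <- config$gan[setdiff(names(config$gan), c("enabled", "per_class"))]
    if (is.null(gargs$image_size)) gargs$image_size <- config$fixture$image_size
    gspec <- do.call(gan_spec, gargs)
    for (cls in class_names(manifest)) {
      fitg <- train_dcgan(manifest, cls, gspec,
                          file.path(run_dir, "gan", cls),
                          seed = derive_seed(seed, "gan", cls),
                          sample_grid = FALSE)
      gan_ckpts[[cls]] <- fitg$checkpoint_path
      if (config$gan$per_class > 0) {
        rows <- generate_labeled(fitg$checkpoint_path, config$gan$per_class,
                                 derive_seed(seed, "gan-sample", cls),
                                 file.path(run_dir, "gan_images"))
        manifest <- new_manifest(dplyr::bind_rows(as_tibble(manifest), rows),
                                 class_names(manifest))
      }
    }
    log_stage("gan", t0, sprintf("checkpoints=%d gan_images=%d",
                                 length(gan_ckpts),
                                 manifest_summary(manifest)$gan))
  }

  if (!dry_run) {
    t0 <- as.numeric(Sys.time())
    fcfg_args <- config$filter
    input <- config$classifier$input
    if (!"filters" %in% names(fcfg_args)) {
      fcfg_args$filters <- if (input == "stacked") {
        c("sobel", "canny", "ckpf", "kernel")
      } else if (input == "raw") character(0) else input
    }
    fcfg <- do.call(filter_config, fcfg_args)
    if (length(fcfg$filters) > 0) {
      manifest <- run_filtration(manifest, fcfg,
                                 file.path(run_dir, "filtered"))
    }
    log_stage("filter", t0,
              sprintf("renderings=%d", sum(manifest$provenance == "filtered")))
  } else {
    fcfg <- do.call(filter_config,
                    utils::modifyList(config$filter,
                                      list(filters = character(0))))
  }

  t0 <- as.numeric(Sys.time())
  manifest <- train_val_split(manifest, config$split$train_fraction,
                              derive_seed(seed, "split"), strict = FALSE)
  s <- manifest_summary(manifest)
  log_stage("split", t0, sprintf("train=%d val=%d", s$train, s$val))

  iso <- verify_isolation(manifest)
  stop_if_not(iso$pass, "isolation check failed with %d violations",
              iso$n_violations)

  fit <- NULL
  report <- NULL
  metrics <- NULL
  if (!dry_run) {
    t0 <- as.numeric(Sys.time())
    cargs <- config$classifier
    spec <- classifier_spec(
      in_channels = if (cargs$input == "stacked") 4L else 1L,
      stem_channels = cargs$stem_channels,
      atrous_channels = cargs$atrous_channels,
      n_classes = length(class_names(manifest)),
      use_pre_context = cargs$use_pre_context %||% TRUE,
      use_post_context = cargs$use_post_context %||% TRUE
    )
    fit <- train_classifier(
      manifest, spec,
      list(epochs = cargs$epochs, batch_size = cargs$batch_size,
           lr = cargs$lr, seed = derive_seed(seed, "classifier"),
           input = cargs$input, early_stop_acc = cargs$early_stop_acc,
           filter_config = fcfg),
      out_dir = file.path(run_dir, "classifier"))
    log_stage("classifier", t0,
              sprintf("epochs=%d best=%d", nrow(fit$history), fit$best_epoch))

    t0 <- as.numeric(Sys.time())
    te <- manifest[manifest$split == "test" &
                     manifest$provenance != "filtered", ]
    x_te <- load_classifier_input(manifest, te, cargs$input, fcfg)
    pred <- predict(fit, x_te)
    cm <- confusion(match(te$class, class_names(manifest)),
                    match(pred, class_names(manifest)),
                    length(class_names(manifest)))
    metrics <- metrics_from_confusion(cm, class_names(manifest))
    report <- list(confusion = cm, metrics = metrics,
                   failure = failure_summary(cm, class_names(manifest)))
    log_stage("evaluate", t0,
              sprintf("test_accuracy=%.2f%%", metrics$accuracy[1]))
  }

  summary <- list(
    seed = seed,
    counts = manifest_summary(manifest),
    # per-class post-augmentation totals (test and filtered rows excluded)
    per_class_total = if (s$total > 0) {
      nonf <- manifest[manifest$provenance != "filtered" &
                         manifest$split != "test", ]
      as.list(table(factor(nonf$class, class_names(manifest))))
    } else list(),
    isolation = list(pass = iso$pass, violations = iso$n_violations),
    test_accuracy = if (!is.null(metrics)) metrics$accuracy[1] else NULL
  )
  jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(summary = summary, manifest = manifest, fit = fit,
                 report = report, run_dir = run_dir),
            class = "nut_pipeline_run")
}

#' @export
print.nut_pipeline_run <- function(x, ...) {
  s <- x$summary$counts
  cat("<nut_pipeline_run>", x$run_dir, "\n")
  cat(sprintf("  originals=%d test=%d pool=%d augmented=%d gan=%d\n",
              s$originals, s$test, s$pool, s$augmented, s$gan))
  cat(sprintf("  train=%d val=%d total=%d\n", s$train, s$val, s$total))
  if (!is.null(x$summary$test_accuracy)) {
    cat(sprintf("  test accuracy: %.2f%%\n", x$summary$test_accuracy))
  }
  invisible(x)
}
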