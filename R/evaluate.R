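#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred equal-length vectors of 1-based integer labels (or
#'   values coercible to them) in `1..n_classes`.
#' @param n_classes number of classes.
#' @return integer `n_classes x n_classes` matrix, rows = true class,
#'   columns = predicted class.
#' @export
#' @examples
#' confusion(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
confusion <- function(y_true, y_pred, n_classes) {
  stop_if_not(length(y_true) == length(y_pred),
              "label vectors differ in length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stop_if_not(all(y_true >= 1 & y_true <= n_classes) &&
                all(y_pred >= 1 & y_pred <= n_classes),
              "labels out of range")
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Per-class and macro metrics from a confusion matrix
#'
#' For each class: TP/FP/FN/TN one-vs-rest, precision `TP/(TP+FP)`,
#' recall = sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1 (harmonic
#' mean of precision and recall) and IoU `TP/(TP+FP+FN)` (the multi-class
#' Jaccard reading). The macro row is the unweighted class mean; accuracy is
#' `trace/total`. All values are percentages. Zero-denominator cases are
#' reported as 0 and flagged in `degenerate`. Sensitivity and recall are the
#' same quantity; both columns are kept to mirror the usual reporting tables.
#'
#' @param cm confusion matrix (rows = true).
#' @param class_names_vec optional class names.
#' @return a tibble, one row per class plus a `"macro"` row, with an
#'   `accuracy` attribute repeated in every row.
#' @export
metrics_from_confusion <- function(cm, class_names_vec = NULL) {
  stop_if_not(sum(cm) > 0, "empty confusion matrix")
  k <- nrow(cm)
  total <- sum(cm)
  nm <- class_names_vec %||% paste0("class_", seq_len(k))
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  rows <- purrr::map(seq_len(k), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    precision <- 100 * safe_div(tp, tp + fp)
    recall <- 100 * safe_div(tp, tp + fn)
    tibble(class = nm[c], tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall,
           sensitivity = recall,
           specificity = 100 * safe_div(tn, tn + fp),
           f1 = safe_div(2 * precision * recall, precision + recall),
           iou = 100 * safe_div(tp, tp + fp + fn),
           degenerate = (tp + fp == 0) | (tp + fn == 0))
  })
  per_class <- dplyr::bind_rows(rows)
  macro <- per_class %>%
    dplyr::summarise(dplyr::across(c("precision", "recall", "sensitivity",
                                     "specificity", "f1", "iou"), mean))
  out <- dplyr::bind_rows(
    per_class,
    tibble(class = "macro", tp = NA_integer_, fp = NA_integer_,
           fn = NA_integer_, tn = NA_integer_) %>%
      dplyr::bind_cols(macro) %>%
      dplyr::mutate(degenerate = any(per_class$degenerate))
  )
  out$accuracy <- 100 * sum(diag(cm)) / total
  out
}

#' Failure summary (misclassified counts and error rates per class)
#'
#' Per class the misclassified count is the row sum minus the diagonal and
#' the error rate is `misclassified / row sum * 100`. The totals row sums the
#' counts and reports **both** aggregate error-rate derivations: the
#' unweighted mean of the per-class error-rate column
#' (`error_rate_mean_of_classes`) and the overall pooled rate
#' (`misclassified_total / n_total * 100`, `error_rate_pooled`). The two
#' differ whenever class error rates differ; both are emitted side by side.
#'
#' @param cm confusion matrix.
#' @param class_names_vec optional class names.
#' @param iou_per_class optional externally supplied per-class IoU values to
#'   aggregate in the totals row (their unweighted mean and SD).
#' @return list with `per_class` tibble and `totals` one-row tibble.
#' @export
failure_summary <- function(cm, class_names_vec = NULL, iou_per_class = NULL) {
  k <- nrow(cm)
  nm <- class_names_vec %||% paste0("class_", seq_len(k))
  n_class <- rowSums(cm)
  mis <- n_class - diag(cm)
  rate <- ifelse(n_class == 0, 0, 100 * mis / n_class)
  per_class <- tibble(class = nm, n = as.integer(n_class),
                      misclassified = as.integer(mis),
                      error_rate = rate)
  if (!is.null(iou_per_class)) per_class$iou <- iou_per_class
  totals <- tibble(
    n = sum(n_class), misclassified = as.integer(sum(mis)),
    error_rate_mean_of_classes = mean(rate),
    error_rate_pooled = ifelse(sum(n_class) == 0, 0,
                               100 * sum(mis) / sum(n_class))
  )
  if (!is.null(iou_per_class)) {
    totals$mean_iou <- mean(iou_per_class)
    totals$sd_iou <- stats::sd(iou_per_class)
  }
  list(per_class = per_class, totals = totals)
}

#' Fold statistics: mean, sample SD and 95% confidence intervals
#'
#' Builds a `fold_stats` object from per-fold metric values. The confidence
#' interval is reported with both the Student-t multiplier (`df = k - 1`) and
#' the normal multiplier (1.96), labelled accordingly.
#'
#' @param values numeric vector of per-fold values, or a data frame of
#'   per-fold metric columns.
#' @param metric name used when `values` is a vector.
#' @return a `fold_stats` object (tibble of per-metric summaries plus the
#'   raw fold values).
#' @export
#' @examples
#' fold_stats(c(99.78, 99.81, 99.80, 99.79, 99.83))
fold_stats <- function(values, metric = "accuracy") {
  tb <- if (is.data.frame(values)) as_tibble(values) else
    tibble(!!metric := values)
  k <- nrow(tb)
  stop_if_not(k >= 2, "need at least two folds")
  summ <- purrr::map(names(tb), function(nm) {
    v <- tb[[nm]]
    m <- mean(v)
    s <- stats::sd(v)
    half_t <- stats::qt(0.975, k - 1) * s / sqrt(k)
    half_z <- 1.96 * s / sqrt(k)
    tibble(metric = nm, k = k, mean = m, sd = s,
           ci_lo_t = m - half_t, ci_hi_t = m + half_t,
           ci_lo_z = m - half_z, ci_hi_z = m + half_z)
  }) %>% dplyr::bind_rows()
  structure(list(summary = summ, folds = tb), class = "fold_stats")
}

#' @export
print.fold_stats <- function(x, ...) {
  cat("<fold_stats>", nrow(x$folds), "folds\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.2f +- %.2f (95%% CI t: [%.2f, %.2f])\n",
                s$metric[i], s$mean[i], s$sd[i], s$ci_lo_t[i], s$ci_hi_t[i]))
  }
  invisible(x)
}

#' Paired t-test between two per-fold metric vectors
#'
#' Standard paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` with
#' `d = a - b` and a two-tailed p-value from the Student-t distribution with
#' `n - 1` degrees of freedom. Zero-variance differences are reported as
#' degenerate (`t = NA`) rather than infinite. p-values below 1e-4 are
#' formatted as `"< 0.0001"` in `p_label`.
#'
#' @param metric_a,metric_b equal-length numeric vectors (length >= 2).
#' @return a one-row tibble: `mean_difference`, `t`, `df`, `p`, `p_label`,
#'   `degenerate`.
#' @export
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))
paired_ttest <- function(metric_a, metric_b) {
  stop_if_not(length(metric_a) == length(metric_b),
              "fold vectors differ in length")
  stop_if_not(length(metric_a) >= 2, "need at least two folds")
  d <- metric_a - metric_b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(tibble(mean_difference = md, t = NA_real_, df = n - 1L,
                  p = NA_real_, p_label = "degenerate (zero variance)",
                  degenerate = TRUE))
  }
  t_stat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  tibble(mean_difference = md, t = t_stat, df = n - 1L, p = p,
         p_label = if (p < 1e-4) "< 0.0001" else sprintf("%.4f", p),
         degenerate = FALSE)
}

#' Stratified k-fold cross-validation over the non-test pool
#'
#' Folds are drawn only from non-test records (the held-out test set never
#' enters cross-validation) with per-class fold sizes differing by at most
#' one. `train_fn(train_rows, heldout_rows, fold)` must return a named
#' numeric vector of metrics for the fold.
#'
#' @param manifest the manifest.
#' @param k number of folds (>= 2).
#' @param train_fn fold runner, see above.
#' @param seed integer seed for the stratified shuffle.
#' @param provenances provenance values eligible for folding.
#' @return a `fold_stats` object over the per-fold metric vectors.
#' @export
kfold_cv <- function(manifest, k = 5, train_fn, seed = 1,
                     provenances = c("original", "augmented", "gan")) {
  stop_if_not(k >= 2, "k must be >= 2")
  pool <- manifest[manifest$split != "test" &
                     manifest$provenance %in% provenances, ]
  counts <- table(factor(pool$class, class_names(manifest)))
  stop_if_not(all(counts >= k), "every class needs at least k members")
  fold_of <- integer(nrow(pool))
  for (cls in class_names(manifest)) {
    ids <- sort(which(pool$class == cls))
    ids <- with_seed(derive_seed(seed, "cv", cls), sample(ids))
    fold_of[ids] <- rep_len(seq_len(k), length(ids))
  }
  res <- purrr::map(seq_len(k), function(f) {
    m <- train_fn(pool[fold_of != f, ], pool[fold_of == f, ], f)
    as_tibble(as.list(m))
  })
  fold_stats(dplyr::bind_rows(res))
}

#' Default ablation variant table
#'
#' The architectural/preprocessing toggles whose combinations make up the
#' ablation study: input rendering (raw vs CKPF), color handling, the
#' pre-/post-context blocks and GAN augmentation.
#'
#' @return a tibble of named variants.
#' @export
default_ablation_variants <- function() {
  tibble(
    variant = c("raw_default_atrous", "raw_pre_context", "raw_post_context",
                "ckpf_default_atrous", "ckpf_pre_context", "ckpf_post_context",
                "ckpf_pre_post_context", "raw_pre_post_context"),
    input = c("raw", "raw", "raw", "ckpf", "ckpf", "ckpf", "ckpf", "raw"),
    pre_context = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    post_context = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    gan_augment = FALSE
  )
}

#' Run an ablation grid
#'
#' Executes one training/evaluation run per variant row and emits one result
#' row per variant: accuracy, mean/variance/SD of the per-class recalls, and
#' macro precision, recall, IoU and F-score.
#'
#' @param manifest the manifest (train/val/test assigned).
#' @param variants tibble like [default_ablation_variants()].
#' @param train_cfg base training configuration for [train_classifier()].
#' @param base_spec base [classifier_spec()] toggled per variant.
#' @param runner optional custom runner `function(variant_row) -> confusion
#'   matrix` (used for cheap contract tests); the default trains the
#'   classifier per variant and evaluates the test split.
#' @param seed integer seed.
#' @return a tibble with one row per variant.
#' @export
ablation_grid <- function(manifest, variants = default_ablation_variants(),
                          train_cfg = list(), base_spec = classifier_spec(),
                          runner = NULL, seed = 1) {
  needed <- c("variant", "input", "pre_context", "post_context")
  stop_if_not(all(needed %in% names(variants)), "variants table incomplete")
  stop_if_not(all(variants$input %in% c("raw", "ckpf", "sobel", "canny",
                                        "kernel", "gray", "stacked")),
              "invalid input toggle")
  run_one <- runner %||% function(v) {
    spec <- base_spec
    spec$use_pre_context <- v$pre_context
    spec$use_post_context <- v$post_context
    cfg <- utils::modifyList(train_cfg, list(input = v$input, seed = seed))
    fit <- train_classifier(manifest, spec, cfg, out_dir = NULL)
    te <- manifest[manifest$split == "test" &
                     manifest$provenance != "filtered", ]
    x_te <- load_classifier_input(manifest, te, v$input,
                                  cfg$filter_config %||% filter_config())
    pred <- predict(fit, x_te)
    confusion(match(te$class, class_names(manifest)),
              match(pred, class_names(manifest)),
              length(class_names(manifest)))
  }
  purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    cm <- run_one(v)
    mt <- metrics_from_confusion(cm)
    macro <- mt[mt$class == "macro", ]
    per <- mt[mt$class != "macro", ]
    tibble(variant = v$variant, input = v$input,
           pre_context = v$pre_context, post_context = v$post_context,
           accuracy = macro$accuracy[1], mean = mean(per$recall),
           variance = stats::var(per$recall), sd = stats::sd(per$recall),
           precision = macro$precision, recall = macro$recall,
           iou = macro$iou, f_score = macro$f1)
  }) %>% dplyr::bind_rows()
}
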