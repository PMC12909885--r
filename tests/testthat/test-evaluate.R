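test_that("confusion matrices count (true, predicted) pairs", {
  expect_equal(confusion(c(1, 1, 2, 2), c(1, 2, 2, 2), 2),
               matrix(c(1L, 0L, 1L, 2L), 2))
  y <- c(3, 1, 2, 3, 3)
  cm <- confusion(y, y, 3)
  expect_equal(diag(cm), c(1L, 1L, 3L))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  set.seed(1)
  for (i in 1:5) {
    yt <- sample(1:4, 30, replace = TRUE)
    yp <- sample(1:4, 30, replace = TRUE)
    cm <- confusion(yt, yp, 4)
    expect_equal(rowSums(cm), as.vector(table(factor(yt, 1:4))),
                 ignore_attr = TRUE)
  }
  expect_error(confusion(c(1, 5), c(1, 1), 4), "out of range")
  expect_error(confusion(1:3, 1:2, 3), "length")
})

test_that("metrics match the hand-worked two-class example", {
  cm <- matrix(c(8, 1, 2, 9), 2)  # [[8,2],[1,9]] rows = true
  mt <- metrics_from_confusion(cm)
  expect_equal(mt$accuracy[1], 100 * 17 / 20)
  c0 <- mt[mt$class == "class_1", ]
  expect_equal(c0$precision, 100 * 8 / 9, tolerance = 1e-12)
  expect_equal(c0$recall, 80)
  expect_equal(c0$sensitivity, c0$recall)
  expect_equal(c0$iou, 100 * 8 / 11, tolerance = 1e-12)
  expect_equal(c0$f1, 100 * 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)
  perfect <- metrics_from_confusion(diag(5L))
  expect_true(all(abs(perfect$precision - 100) < 1e-12))
  expect_true(all(abs(perfect$iou - 100) < 1e-12))
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("macro metrics are invariant under class relabelling", {
  set.seed(2)
  yt <- sample(1:4, 60, replace = TRUE)
  yp <- sample(1:4, 60, replace = TRUE)
  m1 <- metrics_from_confusion(confusion(yt, yp, 4))
  perm <- c(3, 1, 4, 2)
  m2 <- metrics_from_confusion(confusion(perm[yt], perm[yp], 4))
  for (col in c("precision", "recall", "specificity", "f1", "iou")) {
    expect_equal(m1[[col]][m1$class == "macro"],
                 m2[[col]][m2$class == "macro"], tolerance = 1e-12)
  }
})

test_that("every metric equals a brute-force per-sample recount", {
  set.seed(3)
  for (trial in 1:200) {
    n <- sample(2:50, 1)
    yt <- sample(1:8, n, replace = TRUE)
    yp <- sample(1:8, n, replace = TRUE)
    mt <- metrics_from_confusion(confusion(yt, yp, 8))
    want <- brute_metrics(yt, yp, 8)
    for (c in 1:8) {
      row <- mt[mt$class == paste0("class_", c), ]
      for (nm in names(want[[c]])) {
        expect_equal(row[[nm]], unname(want[[c]][nm]), tolerance = 1e-12)
      }
    }
    expect_equal(mt$accuracy[1], 100 * mean(yt == yp), tolerance = 1e-12)
  }
})

test_that("failure summary reproduces both error-rate derivations", {
  # eight classes, 100 test images each, misclassified 3,3,1,3,3,4,6,2
  mis <- c(3, 3, 1, 3, 3, 4, 6, 2)
  cm <- diag(100L - as.integer(mis))
  for (i in 1:8) {
    j <- if (i < 8) i + 1 else 1
    cm[i, j] <- mis[i]
  }
  fs <- failure_summary(cm)
  expect_equal(fs$per_class$misclassified, as.integer(mis))
  expect_equal(fs$totals$misclassified, 25L)
  expect_equal(fs$totals$n, 800)
  expect_equal(fs$per_class$error_rate, mis)
  expect_equal(fs$totals$error_rate_mean_of_classes, mean(mis))
  expect_equal(fs$totals$error_rate_pooled, 100 * 25 / 800)
  perfect <- failure_summary(diag(10L))
  expect_true(all(perfect$per_class$misclassified == 0))
  expect_equal(perfect$totals$error_rate_pooled, 0)
})

test_that("fold statistics reproduce the published 5-fold summary", {
  folds <- c(99.78, 99.81, 99.80, 99.79, 99.83)
  fs <- fold_stats(folds)
  expect_equal(round(fs$summary$mean, 2), 99.80)
  expect_equal(round(fs$summary$sd, 2), 0.02)
  # CI contract: half-width is the t multiplier times sd/sqrt(k)
  expect_equal(fs$summary$ci_hi_t - fs$summary$mean,
               qt(0.975, 4) * sd(folds) / sqrt(5), tolerance = 1e-12)
  same <- fold_stats(rep(50, 4))
  expect_equal(same$summary$sd, 0)
  expect_error(fold_stats(1), "two folds")
})

test_that("paired t-test matches the closed form and t.test", {
  expect_true(paired_ttest(c(1, 2, 3), c(1, 2, 3))$degenerate)
  hand <- paired_ttest(c(2, 3, 4), c(1, 1, 1))
  expect_equal(hand$mean_difference, 2)
  expect_equal(hand$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(hand$df, 2L)
  dac <- c(99.78, 99.81, 99.79, 99.80, 99.83)
  dense <- c(78.31, 78.42, 78.40, 78.31, 78.55)
  tt <- paired_ttest(dac, dense)
  expect_equal(round(tt$mean_difference, 2), 21.40)
  expect_identical(tt$p_label, "< 0.0001")
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    got <- paired_ttest(a, b)
    want <- t.test(a, b, paired = TRUE)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
  }
  expect_error(paired_ttest(1:3, 1:4), "length")
})

test_that("stratified k-fold cross-validation respects the test fence", {
  man <- dry_manifest(4, 11)
  man <- holdout_test(man, 0.2, seed = 1)
  seen <- list()
  fs <- kfold_cv(man, k = 3, seed = 2, train_fn = function(tr, ho, f) {
    seen[[f]] <<- ho
    expect_false(any(tr$split == "test"))
    expect_false(any(ho$split == "test"))
    expect_equal(length(intersect(tr$id, ho$id)), 0)
    c(accuracy = 90 + f)
  })
  expect_s3_class(fs, "fold_stats")
  expect_equal(fs$folds$accuracy, c(91, 92, 93))
  sizes <- vapply(seen, nrow, integer(1))
  expect_lte(max(sizes) - min(sizes), 4)  # <= 1 per class
  per_class <- vapply(seen, function(h) {
    max(table(factor(h$class, class_names(man)))) -
      min(table(factor(h$class, class_names(man))))
  }, numeric(1))
  expect_true(all(per_class <= 1))
  expect_error(kfold_cv(man, k = 20, seed = 1,
                        train_fn = function(...) c(a = 1)),
               "at least k")
})

test_that("the ablation grid emits one result row per requested variant", {
  man <- dry_manifest(3, 4)
  variants <- default_ablation_variants()
  expect_equal(nrow(variants), 8)
  fake_runner <- function(v) {
    cm <- diag(10L)
    if (!v$pre_context) {
      cm[1, 1] <- 9L
      cm[1, 2] <- 1L
    }
    cm
  }
  grid <- ablation_grid(man, variants, runner = fake_runner)
  expect_equal(nrow(grid), 8)
  expect_identical(grid$variant, variants$variant)
  expect_true(all(c("accuracy", "mean", "variance", "sd", "precision",
                    "recall", "iou", "f_score") %in% names(grid)))
  bad <- variants
  bad$input[1] <- "hsv"
  expect_error(ablation_grid(man, bad, runner = fake_runner),
               "invalid input")
  # the plain-atrous variant is smaller than the dual-context variant
  off <- classifier_spec(use_pre_context = FALSE, use_post_context = FALSE)
  on <- classifier_spec()
  expect_lt(count_parameters(off), count_parameters(on))
})
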