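#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a classifier fit
#'
#' @param x a `nut_classifier`.
#' @param ... unused.
#' @return the per-epoch history tibble (losses and accuracies).
#' @export
tidy.nut_classifier <- function(x, ...) {
  x$history
}

#' One-row summary of a classifier fit
#'
#' @param x a `nut_classifier`.
#' @param ... unused.
#' @export
glance.nut_classifier <- function(x, ...) {
  h <- x$history
  best <- h[x$best_epoch, , drop = FALSE]
  tibble(epochs = nrow(h), best_epoch = x$best_epoch,
         train_acc = best$train_acc, val_acc = best$val_acc,
         parameters = count_parameters(x$spec),
         pre_context = x$spec$use_pre_context,
         post_context = x$spec$use_post_context)
}

#' @export
tidy.fold_stats <- function(x, ...) x$summary

#' @export
glance.fold_stats <- function(x, ...) {
  s <- x$summary[1, ]
  tibble(metric = s$metric, k = s$k, mean = s$mean, sd = s$sd,
         ci_lo = s$ci_lo_t, ci_hi = s$ci_hi_t)
}

#' Training-curve plot for a classifier fit
#'
#' @param object a `nut_classifier`.
#' @param ... unused.
#' @return a ggplot with per-epoch loss and accuracy panels.
#' @export
autoplot.nut_classifier <- function(object, ...) {
  h <- object$history %>%
    tidyr::pivot_longer(-"epoch", names_to = "series") %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::mutate(
      panel = ifelse(grepl("loss", .data$series), "loss", "accuracy"),
      split = ifelse(grepl("train", .data$series), "train", "validation")
    )
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Generator/discriminator loss traces of a GAN fit
#'
#' @param object a `gan_fit` from [train_dcgan()].
#' @param ... unused.
#' @export
autoplot.gan_fit <- function(object, ...) {
  h <- object$history %>%
    dplyr::select("step", "loss_d", "loss_g") %>%
    tidyr::pivot_longer(-"step", names_to = "network")
  ggplot2::ggplot(h, ggplot2::aes(.data$step, .data$value,
                                  colour = .data$network)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param cm confusion matrix (rows = true class).
#' @param class_names_vec optional class names.
#' @param normalize show row-normalized proportions instead of counts.
#' @return a ggplot.
#' @export
plot_confusion <- function(cm, class_names_vec = NULL, normalize = FALSE) {
  k <- nrow(cm)
  nm <- class_names_vec %||% paste0("class_", seq_len(k))
  vals <- if (normalize) {
    sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  } else cm
  df <- tidyr::expand_grid(true = factor(nm, nm),
                           predicted = factor(nm, nm)) %>%
    dplyr::mutate(value = as.vector(t(vals)))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.3f", .data$value) else .data$value),
      size = 3) +
    ggplot2::scale_y_discrete(limits = rev(nm)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "true",
                  fill = if (normalize) "rate" else "count") +
    ggplot2::theme_minimal()
}

#' Error-bar plot of fold statistics
#'
#' @param object a `fold_stats`.
#' @param ... unused.
#' @export
autoplot.fold_stats <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$metric, .data$mean)) +
    ggplot2::geom_col(fill = "#9ecae1") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo_t,
                                        ymax = .data$ci_hi_t), width = 0.2) +
    ggplot2::labs(x = NULL, y = "value (95% CI)") +
    ggplot2::theme_minimal()
}
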