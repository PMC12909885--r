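#' AdamW optimizer with cosine-annealed learning rate
#'
#' Decoupled weight decay (weight decay is applied directly to the parameters,
#' not folded into the gradient) and the usual bias-corrected first/second
#' moment estimates. The learning rate follows a half-cosine from `lr` down to
#' `lr_min` over `t_max` scheduled steps.
#'
#' @param lr base learning rate.
#' @param betas length-2 numeric, exponential decay of the moment estimates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled L2 coefficient.
#' @param t_max total steps for the cosine schedule (`Inf` disables annealing).
#' @param lr_min floor of the annealed learning rate.
#' @return an optimizer environment with `step(layers)` and `current_lr()`.
#' @keywords internal
optim_adamw <- function(lr = 1e-4, betas = c(0.5, 0.999), eps = 1e-8,
                        weight_decay = 0, t_max = Inf, lr_min = 0) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e$current_lr <- function() {
    if (!is.finite(t_max)) return(lr)
    frac <- min(e$t / t_max, 1)
    lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * frac))
  }
  e$step <- function(layers) {
    lr_t <- e$current_lr()
    e$t <- e$t + 1L
    p <- net_params(layers)
    g <- net_grads(layers)
    b1 <- betas[1]; b2 <- betas[2]
    for (nm in names(p)) {
      gi <- g[[nm]]
      if (is.null(e$m[[nm]])) {
        e$m[[nm]] <- gi * 0
        e$v[[nm]] <- gi * 0
      }
      e$m[[nm]] <- b1 * e$m[[nm]] + (1 - b1) * gi
      e$v[[nm]] <- b2 * e$v[[nm]] + (1 - b2) * gi * gi
      mhat <- e$m[[nm]] / (1 - b1^e$t)
      vhat <- e$v[[nm]] / (1 - b2^e$t)
      upd <- mhat / (sqrt(vhat) + eps)
      decay <- if (grepl("\\.W$", nm)) weight_decay else 0
      p[[nm]] <- p[[nm]] - lr_t * (upd + decay * p[[nm]])
    }
    net_set_params(layers, p)
    invisible(lr_t)
  }
  e
}
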