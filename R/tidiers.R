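# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# result tibbles.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted methylation model
#'
#' @param x A `meth_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch training history: `epoch`, `train_loss`,
#'   `val_f1`.
#' @export
tidy.meth_fit <- function(x, ...) x$history

#' One-row summary of a fitted methylation model
#'
#' @param x A `meth_fit`.
#' @param ... Unused.
#' @return Tibble with the setting, mode, loss kind, learning rate,
#'   epochs run, best epoch and best validation minor-class F1.
#' @export
glance.meth_fit <- function(x, ...) {
  tibble::tibble(setting = x$plan$setting %||% NA_character_,
                 mode = x$model$mode,
                 loss = x$loss$kind,
                 learning_rate = x$config$learning_rate,
                 n_epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_f1 = x$best_val_f1)
}

#' Plot a training history
#'
#' @param object A `meth_fit`.
#' @param ... Unused.
#' @return A ggplot: training loss and validation minor-class F1 by epoch.
#' @export
autoplot.meth_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_f1"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot a confidence-retention curve
#'
#' @param object A `meth_tau_curve` from [tau_curve()].
#' @param ... Unused.
#' @return A ggplot of minor-class F1 and retained fraction against tau.
#' @export
autoplot.meth_tau_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("f1_minor", "fraction_retained"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$tau, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = NULL, colour = NULL)
}

#' Plot coverage before and after imputation
#'
#' @param object An `imputed_profile` from [impute_profile()].
#' @param ... Unused.
#' @return A ggplot bar chart of the genome-wide CpG coverage rate before
#'   and after imputation.
#' @export
autoplot.imputed_profile <- function(object, ...) {
  d <- tibble::tibble(stage = factor(c("before", "after"),
                                     levels = c("before", "after")),
                      rate = c(attr(object, "rate_before"),
                               attr(object, "rate_after")))
  ggplot2::ggplot(d, ggplot2::aes(.data$stage, .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "CpG coverage rate",
                  title = attr(object, "target_id"))
}
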