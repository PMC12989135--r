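#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-epoch training history of a fit
#'
#' @param x an `abpose_fit`.
#' @param ... unused.
#' @return Tibble with `epoch`, `lr`, `train_loss`, `val_metric`.
#' @exportS3Method generics::tidy
#' @export
tidy.abpose_fit <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' One-row summary of a fit
#'
#' @param x an `abpose_fit`.
#' @param ... unused.
#' @return Tibble with `task`, `epochs_run`, `best_epoch`, `best_val_metric`,
#'   `n_checkpoints`.
#' @exportS3Method generics::glance
#' @export
glance.abpose_fit <- function(x, ...) {
  tibble::tibble(task = x$task, epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_metric = x$best_metric,
                 n_checkpoints = length(x$checkpoints))
}

#' Training-history plot
#'
#' Loss and validation-metric trajectories over epochs.
#'
#' @param object an `abpose_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.abpose_fit <- function(object, ...) {
  h <- tidy(object)
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, what = "training loss"),
    data.frame(epoch = h$epoch, value = h$val_metric,
               what = if (object$task == "classifier") "validation F1" else "validation Pearson r")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Precision at K bar plot
#'
#' @param topk a tibble from [topk_success()].
#' @return A ggplot object.
#' @export
plot_topk <- function(topk) {
  ggplot2::ggplot(topk, ggplot2::aes(x = factor(.data$K), y = .data$precision)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "K", y = "precision@K")
}

#' @importFrom ggplot2 .data
NULL
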