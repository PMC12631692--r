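#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

#' Tidy a fitted network's training history
#'
#' @param x A `molgat_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_rmse`,
#'   `val_rmse`.
#' @method tidy molgat_fit
#' @export
tidy.molgat_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted network
#'
#' @param x A `molgat_fit`.
#' @param ... Unused.
#' @return Tibble: layer type, depth, width, readout, parameter count,
#'   epochs run, best epoch and best validation RMSE.
#' @method glance molgat_fit
#' @export
glance.molgat_fit <- function(x, ...) {
  tibble::tibble(
    layer_type = x$config$layer_type,
    n_layers = x$config$n_layers,
    hidden = x$config$hidden,
    readout = x$config$readout$kind,
    n_parameters = count_parameters(x$model),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_rmse = x$best_val_rmse)
}

#' Training-curve plot
#'
#' @param object A `molgat_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation RMSE per epoch.
#' @method autoplot molgat_fit
#' @export
autoplot.molgat_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "rmse")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "RMSE", color = NULL) +
    ggplot2::theme_minimal()
}

#' Node-position report plot
#'
#' @param object A `molgat_report` from [node_position_report()].
#' @param ... Unused.
#' @return A ggplot bar chart of RMSE per readout strategy.
#' @method autoplot molgat_report
#' @export
autoplot.molgat_report <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), is.finite(.data$rmse))
  d$strategy <- factor(d$strategy, levels = readout_kinds())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strategy, y = .data$rmse)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "test RMSE") +
    ggplot2::theme_minimal()
}

#' Prediction-versus-truth scatter plot
#'
#' @param data A tibble with `target` and `pred` columns (from
#'   [predict.molgat_fit()]).
#' @return A ggplot scatter of predictions against ground truth.
#' @export
plot_predictions <- function(data) {
  stopifnot(all(c("target", "pred") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$target, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "measured", y = "predicted") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
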