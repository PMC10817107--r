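# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a confusion matrix into long form
#'
#' @param x A `sleep_confusion`.
#' @param ... Unused.
#' @return Tibble with `true`, `predicted`, `n`.
#' @export
tidy.sleep_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    true = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    predicted = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    n = as.integer(m)
  )
}

#' Tidy per-class metrics
#'
#' @param x A `stage_metrics`.
#' @param ... Unused.
#' @return Long tibble with `class`, `metric`, `value`.
#' @export
tidy.stage_metrics <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("class", "sensitivity", "specificity",
                             "precision", "f1", "binary_accuracy")],
    -"class", names_to = "metric", values_to = "value"
  )
}

#' One-row summary of a metrics report
#'
#' @param x A `stage_metrics`.
#' @param ... Unused.
#' @return Tibble with overall accuracy, the macro metrics and the count
#'   of classes excluded from macro averaging.
#' @export
glance.stage_metrics <- function(x, ...) {
  macro <- attr(x, "macro")
  tibble::tibble(
    overall_accuracy = attr(x, "overall_accuracy"),
    macro_sensitivity = macro[["sensitivity"]],
    macro_specificity = macro[["specificity"]],
    macro_precision = macro[["precision"]],
    macro_f1 = macro[["f1"]],
    n_excluded = attr(x, "n_excluded")
  )
}

#' Tidy a model's layer table
#'
#' @param x A `sleep_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per layer: kind, output shape, parameters.
#' @export
tidy.sleep_cnn <- function(x, ...) {
  pc <- layer_parameter_counts(x$spec)
  geom <- x$geometry
  pc$output <- vapply(geom, function(g) {
    paste(c(g$h, g$w, g$c), collapse = "x")
  }, "")
  pc
}

#' One-row training summary of a model
#'
#' @param x A `sleep_cnn`.
#' @param ... Unused.
#' @return Tibble with layer/parameter counts and, when trained, final
#'   loss and last validation accuracy.
#' @export
glance.sleep_cnn <- function(x, ...) {
  h <- x$history
  va <- if (!is.null(h) && any(!is.na(h$val_accuracy))) {
    utils::tail(h$val_accuracy[!is.na(h$val_accuracy)], 1)
  } else NA_real_
  tibble::tibble(
    n_layers = count_layers(x$spec),
    n_params = sum(layer_parameter_counts(x$spec)$n_params),
    trained = x$trained,
    iterations = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else utils::tail(h$loss, 1),
    val_accuracy = va
  )
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' Mean and standard deviation across folds
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Wide one-row tibble of `<metric>_mean` / `<metric>_sd`.
#' @export
glance.cv_result <- function(x, ...) {
  s <- x$summary
  out <- c(stats::setNames(s$mean, paste0(s$metric, "_mean")),
           stats::setNames(s$sd, paste0(s$metric, "_sd")))
  tibble::as_tibble(as.list(out))
}

#' Plot a scalogram
#'
#' Heat map of transform magnitude over time and (log-spaced) frequency.
#'
#' @param object A `scalogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    frequency = object$frequencies,
    time = object$times
  )
  df$magnitude <- as.vector(t(object$magnitude))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "|CWT|") +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Loss per iteration and validation accuracy where recorded.
#'
#' @param object A trained `sleep_cnn`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleep_cnn <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  long <- dplyr::bind_rows(
    tibble::tibble(iteration = h$iteration, value = h$loss, curve = "loss"),
    tibble::tibble(iteration = h$iteration, value = h$val_accuracy,
                   curve = "validation accuracy")
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Tile plot with counts, rows = true stage, columns = predicted.
#'
#' @param object A `sleep_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleep_confusion <- function(object, ...) {
  df <- tidy.sleep_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted stage", y = "true stage", fill = "count") +
    ggplot2::theme_minimal()
}
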