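# ggplot2 views of profiles, importance traces, prediction distributions
# and the training studies.

#' @export
autoplot.swaxs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  title = attr(object, "condition")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.waxs_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$importance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = sprintf("normalized %s importance", object$kind[1]),
                  title = object$descriptor[1]) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.waxs_prediction <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$histogram$upper - object$histogram$lower,
                      fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2) +
    ggplot2::labs(x = object$descriptor, y = "count",
                  title = sprintf("prediction distribution (alpha = %g)",
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.waxs_model <- function(object, kind = "gain", ...) {
  autoplot(importance_trace(object, kind = kind))
}

#' Plot a learning-curve trace
#'
#' @param trace Output of [learning_curve()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$size, y = .data$test_metric,
                                      group = .data$seed)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training profiles", y = "test metric") +
    ggplot2::theme_minimal()
}

#' Plot a noise-study trace
#'
#' @param trace Output of [noise_study()].
#' @return A ggplot object.
#' @export
plot_noise_study <- function(trace) {
  long <- tidyr::pivot_longer(trace, c("train_metric", "val_metric", "test_metric"),
                              names_to = "split", values_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$metric,
                                     colour = .data$split, group = interaction(.data$split, .data$seed))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative noise level", y = "metric") +
    ggplot2::theme_minimal()
}

#' Plot an under-sampling study
#'
#' @param study Output of [undersampling_study()].
#' @return A ggplot object with the Shannon channel count marked.
#' @export
plot_undersampling <- function(study) {
  ggplot2::ggplot(study$trace, ggplot2::aes(x = .data$n_points,
                                            y = .data$test_metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = study$shannon_channels, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "q points", y = "test metric") +
    ggplot2::theme_minimal()
}
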