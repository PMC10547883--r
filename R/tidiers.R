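#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-class metrics
#'
#' @param x an `fp_metrics` report.
#' @param ... unused.
#' @return a tibble with one row per class: TP/FP/FN counts and
#'   precision/recall/F1.
#' @export
tidy.fp_metrics <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x an `fp_metrics` report.
#' @param ... unused.
#' @return a one-row tibble: accuracy, macro precision/recall/F1, n_test.
#' @export
glance.fp_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 n_test = x$n_test)
}

#' One-row summary of a fitted classifier
#'
#' @param x an `fp_classifier`.
#' @param ... unused.
#' @return a one-row tibble: chosen alpha, class/feature/train counts and
#'   the CV scheme used for the regularization path.
#' @export
glance.fp_classifier <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_classes = length(x$class_list),
                 n_features = length(x$center), n_train = x$n_train,
                 cv_method = x$cv_method)
}

#' Tidy a parameter sweep
#'
#' @param x an `fp_sweep`.
#' @param ... unused.
#' @return a tibble with one row per grid value: mean/min/max accuracy.
#' @export
tidy.fp_sweep <- function(x, ...) {
  dplyr::mutate(x$summary, axis = x$axis, n_repeats = x$n_repeats,
                .before = 1L)
}

#' Tidy a cross-over matrix
#'
#' @param x an `fp_crossover`.
#' @param ... unused.
#' @return a long tibble with one row per (train session, test session)
#'   cell and its mean accuracy.
#' @export
tidy.fp_crossover <- function(x, ...) x$summary

#' Tidy a leave-one-out evaluation
#'
#' @param x an `fp_loom`.
#' @param ... unused.
#' @return a tibble with one row per left-out subject.
#' @export
tidy.fp_loom <- function(x, ...) x$per_run

#' Mean/sd summary of a leave-one-out evaluation
#'
#' @param x an `fp_loom`.
#' @param ... unused.
#' @return a tibble with mean and sd per metric across left-out runs.
#' @export
glance.fp_loom <- function(x, ...) x$summary

#' Plot a parameter sweep as a mean line with min-max ribbon
#'
#' @param object an `fp_sweep`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fp_sweep <- function(object, ...) {
  lab <- switch(object$axis, num_kernels = "number of kernels",
                num_trials = "training trials per subject",
                duration = "trial duration (s)")
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_accuracy,
                                      ymax = .data$max_accuracy),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_accuracy), color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_accuracy), color = "steelblue") +
    ggplot2::labs(x = lab, y = "accuracy",
                  title = sprintf("Identification accuracy vs %s (%d repeats)",
                                  lab, object$n_repeats)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-over matrix as an annotated tile grid
#'
#' @param object an `fp_crossover`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fp_crossover <- function(object, ...) {
  d <- object$summary
  d$train_session <- factor(d$train_session, c("rs1", "rs2", "empty"))
  d$test_session <- factor(d$test_session, c("rs1", "rs2", "empty"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test_session, y = .data$train_session,
                                  fill = .data$mean_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$mean_accuracy))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "test session", y = "train session", fill = "accuracy",
                  title = "Train/test session cross-over") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
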