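# ggplot2 autoplot methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a training run
#'
#' Loss and training accuracy (plus validation AUC when logged) per epoch.
#'
#' @param object A `cvit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvit_fit
#' @export
autoplot.cvit_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              cols = c("loss", "train_accuracy", "val_auc"),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training run") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `cvit_eval` with labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvit_eval
#' @export
autoplot.cvit_eval <- function(object, ...) {
  if (is.null(object$roc)) stop("scores-only evaluation has no ROC", call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve of a LASSO selection
#'
#' Binomial deviance (with one-SE ribbon) against log lambda; the optimum is
#' marked.
#'
#' @param object A `cvit_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvit_selection
#' @export
autoplot.cvit_selection <- function(object, ...) {
  df <- tibble::tibble(log_lambda = log(object$lambda_path),
                       deviance = object$cv_deviance, se = object$cv_se)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_lambda, y = .data$deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$deviance - .data$se,
                                      ymax = .data$deviance + .data$se),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_opt), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "CV binomial deviance",
                  title = sprintf("%d features selected", object$n_selected)) +
    ggplot2::theme_minimal()
}

#' Plot a per-layer complexity report
#'
#' @param object A `cvit_complexity` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvit_complexity
#' @export
autoplot.cvit_complexity <- function(object, ...) {
  df <- object
  df$layer <- factor(df$layer, levels = rev(df$layer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flops, y = .data$layer,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "multiply operations (log scale)", y = NULL,
                  title = "Per-layer computational cost") +
    ggplot2::theme_minimal()
}
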