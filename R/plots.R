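#' Observed-versus-predicted plot for a fitted model
#'
#' @param object A `qsar_fit`.
#' @param ... Unused.
#' @return A ggplot: observed activity against model prediction with the
#'   identity line.
#' @export
autoplot.qsar_fit <- function(object, ...) {
  df <- prediction_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("%s: observed vs predicted %s", object$spec$label,
                      object$spec$response),
      subtitle = sprintf("n = %d, R2 = %.2f, s = %.4f", object$n,
                         object$r.squared, object$sigma),
      x = sprintf("predicted %s", object$spec$response),
      y = sprintf("observed %s", object$spec$response)
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a cross-validation result
#'
#' For leave-one-out results, observed activity against the held-out
#' prediction; for leave-N-out, the distribution of per-repetition Q2.
#'
#' @param object A `qsar_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qsar_cv <- function(object, ...) {
  if (!is.null(object$predictions)) {
    ggplot2::ggplot(object$predictions,
                    ggplot2::aes(x = .data$predicted, y = .data$observed)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(
        title = sprintf("%s held-out predictions", object$kind),
        subtitle = sprintf("PRESS = %.4f, Q2 = %.2f", object$PRESS, object$Q2),
        x = "held-out prediction", y = "observed"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_repetition, ggplot2::aes(x = .data$Q2)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
      ggplot2::geom_vline(xintercept = object$Q2, colour = "firebrick") +
      ggplot2::labs(
        title = sprintf("Leave-%d-out Q2 over %d repetitions", object$N,
                        object$repetitions),
        subtitle = sprintf("mean Q2 = %.2f", object$Q2),
        x = "per-repetition Q2", y = "repetitions"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Tile plot of a correlation matrix
#'
#' @param object A `qsar_cormat`.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise Pearson r.
#' @export
autoplot.qsar_cormat <- function(object, ...) {
  df <- tidy(object)
  vars <- attr(object, "variables")
  df$var1 <- factor(df$var1, levels = vars)
  df$var2 <- factor(df$var2, levels = rev(vars))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(title = sprintf("Pearson correlation (n = %d)", attr(object, "n")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient-recovery plot for a synthetic experiment
#'
#' @param object A `qsar_recovery`.
#' @param ... Unused.
#' @return A ggplot of mean estimate against truth per coefficient, with
#'   RMSE whiskers.
#' @export
autoplot.qsar_recovery <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), shape = 4, size = 3,
                        colour = "firebrick") +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_estimate,
                                          ymin = .data$mean_estimate - .data$rmse,
                                          ymax = .data$mean_estimate + .data$rmse)) +
    ggplot2::labs(
      title = sprintf("Coefficient recovery over %d replicates",
                      attr(object, "replicates")),
      subtitle = sprintf("mean R2 = %.2f, mean Q2 = %.2f",
                         attr(object, "mean_R2"), attr(object, "mean_Q2")),
      x = NULL, y = "estimate (cross = truth, whiskers = RMSE)"
    ) +
    ggplot2::theme_minimal()
}
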