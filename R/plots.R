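# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_vline geom_tile geom_histogram labs theme_minimal
#'   scale_fill_manual
NULL

#' @export
ggplot2::autoplot

#' Plot a nested-subset sweep
#'
#' ACC/100, AUC and their mean against subset size, with the chosen size
#' marked.
#'
#' @param object A `sweep_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    mutate(object$table, acc = .data$acc / 100),
    c("acc", "auc", "score"), names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$k, y = .data$value,
                   color = .data$metric)) +
    geom_line() +
    geom_vline(xintercept = object$best_k, linetype = "dashed") +
    labs(title = paste0(object$algorithm, " on ", object$family),
         x = "features retained (k)", y = "cross-validated value",
         color = NULL) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(title = sprintf("ROC (AUC = %.3f)", round_half_up(object$auc, 3)),
         x = "false positive rate", y = "true positive rate") +
    theme_minimal()
}

#' Plot a screening result as an evidence-channel grid
#'
#' One row per integrated ingredient, one column per channel, mirroring the
#' membership table layout.
#'
#' @param object A `screening_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.screening_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("in_s1", "in_s2", "in_s3"),
                              names_to = "channel", values_to = "member")
  long$channel <- c(in_s1 = "classifier", in_s2 = "HILI",
                    in_s3 = "network")[long$channel]
  ggplot(long, aes(x = .data$channel,
                   y = factor(.data$ingredient,
                              levels = rev(object$table$ingredient)),
                   fill = .data$member)) +
    geom_tile(color = "grey80") +
    scale_fill_manual(values = c(`TRUE` = "#c23b22", `FALSE` = "grey95")) +
    labs(x = NULL, y = NULL, fill = "member") +
    theme_minimal()
}

#' Plot the Y-randomization accuracy distribution
#'
#' @param object A `yrand_result`.
#' @param reference Optional real-model accuracy to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.yrand_result <- function(object, reference = NULL, ...) {
  p <- ggplot(tibble(acc = object$acc), aes(x = .data$acc)) +
    geom_histogram(bins = 20, fill = "grey70", color = "white") +
    labs(x = "permuted-label CV accuracy (%)", y = "runs",
         title = sprintf("Y-randomization: %.2f +/- %.2f over %d runs",
                         object$mean, object$sd, object$runs)) +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_vline(xintercept = reference, color = "#c23b22")
  }
  p
}
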