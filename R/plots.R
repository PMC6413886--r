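#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Funnel plot of the sequential screens
#'
#' Bar chart of how many candidate pairs survive each screening step.
#'
#' @param network an `sr_network` from [run_sr_screen()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(network) {
  f <- network$audit$funnel
  df <- tibble::tibble(step = factor(names(f), levels = names(f)),
                       pairs = unlist(f))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$pairs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$pairs), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "surviving pairs",
                  title = "Screening funnel") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a rescue network
#'
#' @param object an `sr_network`.
#' @param ... unused.
#' @return A ggplot object (log-log degree frequency).
#' @method autoplot sr_network
#' @export
autoplot.sr_network <- function(object, ...) {
  deg <- table(c(object$edges$vulnerable, object$edges$rescuer))
  df <- dplyr::count(tibble::tibble(degree = as.integer(deg)), .data$degree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node degree", y = "frequency",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' ROC curve from a score evaluation
#'
#' @param roc result of [score_roc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", roc$auc)) +
    ggplot2::theme_minimal()
}

#' Synergism overview for a combination screen
#'
#' Median Bliss synergism per (cell line, inhibitor) grid, colored by
#' call, with the synergy/antagonism thresholds marked.
#'
#' @param calls tibble from [synergy_call()].
#' @return A ggplot object.
#' @export
plot_synergy <- function(calls) {
  df <- calls[!is.na(calls$synergism), ]
  df$grid <- paste(df$cell_line, df$rescuer_inhibitor, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$grid,
                                                      .data$synergism),
                                   y = .data$synergism,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.75, 1.25), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median Bliss synergism") +
    ggplot2::theme_minimal()
}
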