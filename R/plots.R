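# ggplot2 figures for the result objects.

#' Volcano plot of a differential-expression result
#'
#' @param object A `uromir_de` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.uromir_de <- function(object, ...) {
  df <- tidy(object)
  df$neglog10p <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = .data$neglog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("adj. p < %.2g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Bar plot of the bootstrap feature-importance ranking
#'
#' @param object A `uromir_ranking`.
#' @param top Number of top features shown.
#' @param ... Unused.
#' @export
autoplot.uromir_ranking <- function(object, top = 20, ...) {
  df <- utils::head(tidy_ranking(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$mean_importance),
                                   y = .data$mean_importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean total-gain importance") +
    ggplot2::theme_minimal()
}

tidy_ranking <- function(x) as_tibble(unclass(x)[names(x)])

#' ROC curve from labels and scores
#'
#' @inheritParams roc_auc
#' @return A ggplot of the empirical ROC curve, AUC in the subtitle.
#' @export
plot_roc <- function(labels, scores) {
  y <- as.numeric(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(fpr = mean(scores[y == 0] >= t), tpr = mean(scores[y == 1] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", roc_auc(labels, scores))) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object A `uromir_eval`.
#' @param ... Unused.
#' @export
autoplot.uromir_eval <- function(object, ...) {
  plot_roc(object$predictions$label, object$predictions$score) +
    ggplot2::geom_point(
      data = tibble(fpr = 1 - object$specificity, tpr = object$sensitivity),
      colour = "firebrick", size = 2)
}
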