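# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x A `uromir_de` tibble.
#' @param ... Unused.
#' @return The per-miRNA result as a plain tibble.
#' @export
tidy.uromir_de <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.uromir_de
#' @export
glance.uromir_de <- function(x, ...) {
  tibble(n_mirnas = nrow(x), n_significant = sum(x$significant),
         n_up = sum(x$significant & x$log2_fold_change > 0),
         n_down = sum(x$significant & x$log2_fold_change < 0),
         alpha = attr(x, "alpha"))
}

#' Tidy a trained classifier bundle
#'
#' @param x A `uromir_classifier`.
#' @param ... Unused.
#' @return One row per selected feature with its bootstrap importance rank.
#' @export
tidy.uromir_classifier <- function(x, ...) {
  rk <- x$ranking[x$ranking$feature %in% x$features, ]
  tibble(feature = rk$feature, rank = rk$rank,
         mean_importance = rk$mean_importance,
         times_sampled = rk$times_sampled)
}

#' @rdname tidy.uromir_classifier
#' @export
glance.uromir_classifier <- function(x, ...) {
  tibble(learner = x$learner, n_features = length(x$features),
         threshold = x$threshold,
         achieved_sensitivity = x$achieved_sensitivity,
         cv_auc_mean = mean(x$cv_fold_metrics$auc, na.rm = TRUE),
         cv_auc_sd = stats::sd(x$cv_fold_metrics$auc, na.rm = TRUE))
}

#' Tidy an evaluation report
#'
#' @param x A `uromir_eval`.
#' @param ... Unused.
#' @return Long tibble of metrics with interval bounds where defined.
#' @export
tidy.uromir_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "auc", estimate = x$auc,
           lower = NA_real_, upper = NA_real_),
    tibble(metric = "sensitivity", estimate = x$sensitivity,
           lower = x$sensitivity_ci[["lower"]],
           upper = x$sensitivity_ci[["upper"]]),
    tibble(metric = "specificity", estimate = x$specificity,
           lower = x$specificity_ci[["lower"]],
           upper = x$specificity_ci[["upper"]]),
    tibble(metric = "ppv", estimate = x$ppv, lower = NA_real_, upper = NA_real_),
    tibble(metric = "npv", estimate = x$npv, lower = NA_real_, upper = NA_real_))
}

#' @rdname tidy.uromir_eval
#' @export
glance.uromir_eval <- function(x, ...) {
  tibble(n = x$n, auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, ppv = x$ppv, npv = x$npv,
         threshold = x$threshold, prevalence = x$prevalence)
}
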