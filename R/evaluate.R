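# Diagnostic evaluation: ROC/AUC, confusion metrics with Wilson and
# t-based confidence intervals, stage-stratified sensitivity, PPV/NPV under
# an assumed prevalence, CA19-9 comparison at the 37 U/mL clinical cutoff,
# and subgroup-bias association tests.

EARLY_STAGES <- c("0", "IA", "IB", "IIA")
LATE_STAGES <- c("IIB", "III", "IV")

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted half. Invariant under strictly
#' increasing score transforms.
#'
#' @param labels Binary labels (1/TRUE = positive).
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) abort("both classes must be present.")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity at a score threshold
#'
#' Positive call iff score >= threshold.
#'
#' @inheritParams roc_auc
#' @param threshold Score cutoff.
#' @return List: `sensitivity`, `specificity`, and the confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(labels, scores, threshold) {
  y <- as.numeric(labels)
  call <- scores >= threshold
  tp <- sum(call & y == 1); fn <- sum(!call & y == 1)
  tn <- sum(!call & y == 0); fp <- sum(call & y == 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,n Observed successes out of n trials (n >= 1).
#' @param level Confidence level, default 0.95.
#' @return Named vector `lower`, `upper`, both in [0, 1].
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n) {
    abort("need 0 <= successes <= n with n >= 1.")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = (centre - half) / (1 + z^2 / n),
    upper = (centre + half) / (1 + z^2 / n))
}

#' Clopper-Pearson exact interval for a proportion
#'
#' @inheritParams wilson_ci
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n) {
    abort("need 0 <= successes <= n with n >= 1.")
  }
  ci <- stats::binom.test(successes, n, conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' t-based confidence interval for a mean of fold-level metrics
#'
#' mean +/- t(k - 1) * sd / sqrt(k) with the sample standard deviation
#' (n - 1 denominator); the construction used for cross-validation summary
#' metrics.
#'
#' @param fold_values Numeric vector of per-fold metric values (k >= 2).
#' @param level Confidence level.
#' @return Named vector `mean`, `sd`, `lower`, `upper`.
#' @export
t_mean_ci <- function(fold_values, level = 0.95) {
  k <- length(fold_values)
  if (k < 2) abort("need at least 2 fold values.")
  m <- mean(fold_values); s <- stats::sd(fold_values)
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1) * s / sqrt(k)
  c(mean = m, sd = s, lower = m - half, upper = m + half)
}

#' Predictive values under an assumed prevalence
#'
#' ppv = pi s / (pi s + (1 - pi)(1 - c)); npv = (1 - pi) c /
#' ((1 - pi) c + pi (1 - s)) for prevalence pi, sensitivity s,
#' specificity c. A zero denominator yields `NA` with a flag.
#'
#' @param sensitivity,specificity,prevalence All in [0, 1].
#' @return List: `ppv`, `npv`, `flag` (character, `NA` unless degenerate).
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  s <- sensitivity; cc <- specificity; pi <- prevalence
  den_p <- pi * s + (1 - pi) * (1 - cc)
  den_n <- (1 - pi) * cc + pi * (1 - s)
  flag <- NA_character_
  ppv <- if (den_p > 0) pi * s / den_p else { flag <- "ppv_undefined"; NA_real_ }
  npv <- if (den_n > 0) (1 - pi) * cc / den_n else { flag <- "npv_undefined"; NA_real_ }
  list(ppv = ppv, npv = npv, flag = flag)
}

#' Stage-stratified sensitivity
#'
#' Early stage = TNM 0-IIA (localized, resectable); late stage = IIB-IV.
#' Sensitivities are reported with Wilson and Clopper-Pearson intervals;
#' empty groups yield `NA` with zero counts.
#'
#' @param meta Metadata of the scored positive-class samples (`sample_id`,
#'   `stage`); only rows with a TNM stage are used.
#' @param scores Tibble with `sample_id`, `score` (or named numeric vector).
#' @param threshold Positive-call cutoff (score >= threshold).
#' @return Tibble: `group`, `n`, `detected`, `sensitivity`, Wilson and
#'   Clopper-Pearson bounds.
#' @export
stage_stratified_sensitivity <- function(meta, scores, threshold) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$sample_id)
  }
  meta <- meta[meta$stage %in% c(EARLY_STAGES, LATE_STAGES), ]
  meta$score <- scores[meta$sample_id]
  groups <- c(list(early = EARLY_STAGES, late = LATE_STAGES),
              stats::setNames(as.list(unique(meta$stage)), unique(meta$stage)))
  purrr::map_dfr(names(groups), function(g) {
    sub <- meta[meta$stage %in% groups[[g]], ]
    n <- nrow(sub); det <- sum(sub$score >= threshold)
    if (n == 0) {
      return(tibble(group = g, n = 0L, detected = 0L, sensitivity = NA_real_,
                    wilson_lower = NA_real_, wilson_upper = NA_real_,
                    cp_lower = NA_real_, cp_upper = NA_real_))
    }
    w <- wilson_ci(det, n); cp <- clopper_pearson_ci(det, n)
    tibble(group = g, n = n, detected = det, sensitivity = det / n,
           wilson_lower = w[["lower"]], wilson_upper = w[["upper"]],
           cp_lower = cp[["lower"]], cp_upper = cp[["upper"]])
  })
}

#' Classify by CA19-9 at the clinical cutoff
#'
#' Positive iff the level strictly exceeds `cutoff` (37.0 U/mL, the
#' established pancreatic-cancer threshold). Missing measurements are
#' excluded and counted.
#'
#' @param values CA19-9 levels in U/mL (may contain `NA`).
#' @param labels Binary disease labels aligned with `values`.
#' @param cutoff Positivity cutoff, default 37.0.
#' @return List: `sensitivity`, `specificity`, `n_used`, `n_missing`.
#' @export
ca199_classify <- function(values, labels, cutoff = 37.0) {
  if (any(values < 0, na.rm = TRUE)) abort("CA19-9 levels cannot be negative.")
  use <- !is.na(values)
  y <- as.numeric(labels)[use]
  pos_call <- values[use] > cutoff
  list(sensitivity = if (sum(y == 1) > 0) mean(pos_call[y == 1]) else NA_real_,
       specificity = if (sum(y == 0) > 0) mean(!pos_call[y == 0]) else NA_real_,
       n_used = sum(use), n_missing = sum(!use))
}

#' Association between prediction scores and a covariate
#'
#' Method chosen by covariate type: continuous covariates get Pearson and
#' Spearman correlations (the Pearson pair is the headline statistic),
#' two-category covariates a Wilcoxon rank-sum test, covariates with three
#' or more categories a Kruskal-Wallis test. Constant covariates are
#' flagged with p = 1.
#'
#' @param scores Numeric prediction scores.
#' @param covariate Numeric, factor or character covariate (NA dropped
#'   pairwise).
#' @return Tibble: `method`, `statistic`, `p_value`, `n`, plus
#'   `spearman_rho`/`spearman_p` for continuous covariates.
#' @export
subgroup_association <- function(scores, covariate) {
  use <- !is.na(scores) & !is.na(covariate)
  s <- scores[use]; v <- covariate[use]
  if (sum(use) < 3) abort("need at least 3 non-missing pairs.")
  if (length(unique(v)) < 2) {
    return(tibble(method = "constant", statistic = NA_real_, p_value = 1,
                  n = sum(use)))
  }
  if (is.numeric(v) && length(unique(v)) > 8) {
    pe <- stats::cor.test(s, v, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(s, v, method = "spearman",
                                           exact = FALSE))
    tibble(method = "pearson", statistic = unname(pe$estimate),
           p_value = pe$p.value, n = sum(use),
           spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  } else {
    g <- factor(v)
    if (nlevels(g) == 2) {
      wt <- stats::wilcox.test(s ~ g, exact = FALSE)
      tibble(method = "wilcoxon", statistic = unname(wt$statistic),
             p_value = wt$p.value, n = sum(use))
    } else {
      kw <- stats::kruskal.test(s, g)
      tibble(method = "kruskal-wallis", statistic = unname(kw$statistic),
             p_value = kw$p.value, n = sum(use))
    }
  }
}

#' Full diagnostic evaluation of a classifier on a cohort
#'
#' Scores the samples, then reports AUC, sensitivity/specificity with
#' Wilson intervals at the bundle's calibrated threshold, cross-validation
#' fold summaries with t-intervals, stage-stratified sensitivity, PPV/NPV
#' at the stated prevalence, the CA19-9 comparison where levels are
#' available, and subgroup-bias associations (age, sex, total counts,
#' species detected, risk factors, CA19-9).
#'
#' @param bundle A `uromir_classifier`.
#' @inheritParams predict.uromir_classifier
#' @param meta Metadata for the evaluated samples.
#' @param prevalence Assumed disease prevalence for PPV/NPV, default 0.01.
#' @return A `uromir_eval` list.
#' @export
evaluate_classifier <- function(bundle, counts, meta, totals = NULL,
                                prevalence = 0.01) {
  keep <- meta$sample_id[meta$cohort %in% c(bundle$positive, bundle$negative)]
  keep <- intersect(names(counts), keep)
  counts_eval <- counts[, c("mirna", keep)]
  meta_eval <- meta[match(keep, meta$sample_id), ]
  pred <- stats::predict(bundle, counts_eval, meta_eval, totals = totals)
  y <- as.numeric(meta_eval$cohort == bundle$positive)
  cm <- confusion_at_threshold(y, pred$score, bundle$threshold)
  sens_ci <- wilson_ci(cm$tp, cm$tp + cm$fn)
  spec_ci <- wilson_ci(cm$tn, cm$tn + cm$fp)
  pv <- ppv_npv(cm$sensitivity, cm$specificity, prevalence)
  fold <- bundle$cv_fold_metrics
  cv_summary <- purrr::map_dfr(c("auc", "sensitivity", "specificity"),
    function(mm) {
      v <- fold[[mm]][!is.na(fold[[mm]])]
      ci <- t_mean_ci(v)
      tibble(metric = mm, mean = ci["mean"], sd = ci["sd"],
             lower = ci["lower"], upper = ci["upper"])
    })
  stage_tbl <- stage_stratified_sensitivity(
    meta_eval[meta_eval$cohort == bundle$positive, ], pred, bundle$threshold)
  ca <- if ("ca19_9" %in% names(meta_eval) && any(!is.na(meta_eval$ca19_9))) {
    ca199_classify(meta_eval$ca19_9, y)
  } else NULL
  assoc <- subgroup_table(pred$score, meta_eval, counts_eval)
  structure(list(
    auc = roc_auc(y, pred$score),
    sensitivity = cm$sensitivity, sensitivity_ci = sens_ci,
    specificity = cm$specificity, specificity_ci = spec_ci,
    confusion = cm, threshold = bundle$threshold,
    cv_summary = cv_summary, stage_sensitivity = stage_tbl,
    prevalence = prevalence, ppv = pv$ppv, npv = pv$npv,
    ca19_9 = ca, subgroup_associations = assoc,
    predictions = dplyr::bind_cols(pred, tibble(label = y)),
    n = nrow(pred)),
    class = "uromir_eval")
}

subgroup_table <- function(scores, meta, counts) {
  covs <- list(age = meta$age, sex = meta$sex,
               total_counts = unname(count_totals(counts)),
               species_detected = unname(species_detected(counts)))
  if ("ca19_9" %in% names(meta)) covs$ca19_9 <- meta$ca19_9
  if ("risk_factors" %in% names(meta)) {
    hr_rf <- meta$risk_factors
    covs$risk_factors <- ifelse(is.na(hr_rf), NA_character_,
                                vapply(strsplit(hr_rf, ";"), function(v) v[1],
                                       character(1)))
  }
  purrr::map_dfr(names(covs), function(nm) {
    res <- tryCatch(subgroup_association(scores, covs[[nm]]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble(covariate = nm), res)
  })
}

#' @export
print.uromir_eval <- function(x, ...) {
  cat(sprintf("Diagnostic evaluation (n = %d)\n", x$n))
  cat(sprintf("  AUC: %.3f\n", x$auc))
  cat(sprintf("  sensitivity: %.3f (95%% CI %.3f-%.3f)\n",
              x$sensitivity, x$sensitivity_ci["lower"], x$sensitivity_ci["upper"]))
  cat(sprintf("  specificity: %.3f (95%% CI %.3f-%.3f)\n",
              x$specificity, x$specificity_ci["lower"], x$specificity_ci["upper"]))
  cat(sprintf("  PPV/NPV at %.1f%% prevalence: %.3f / %.3f\n",
              100 * x$prevalence, x$ppv, x$npv))
  invisible(x)
}
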