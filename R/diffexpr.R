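# Negative-binomial Wald differential expression between two cohorts, with
# median-of-ratios size factors, Benjamini-Hochberg adjustment and a
# Spearman stage-trend test. This is a deliberately minimal NB-Wald
# analysis: per-miRNA method-of-moments dispersion with a floor, no
# empirical-Bayes dispersion shrinkage, no outlier or independent filtering.

#' Median-of-ratios size factors
#'
#' factor_j = median over all-nonzero miRNAs of counts[i, j] / geomean_i,
#' the standard count-normalization reference for NB differential
#' expression.
#'
#' @inheritParams count_matrix
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_matrix(counts)
  usable <- rowSums(m == 0) == 0
  if (!any(usable)) {
    abort(paste("no miRNA has nonzero counts in every sample;",
                "consider a poscounts-style fallback."))
  }
  log_geo <- rowMeans(log(m[usable, , drop = FALSE]))
  apply(m[usable, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
}

#' Negative-binomial Wald differential expression
#'
#' Per miRNA, fits an NB GLM with log link, design `~ condition`, and
#' log size-factor offsets; dispersion (alpha in Var = mu + alpha mu^2) is a
#' pooled within-group method-of-moments estimate with a small-sample
#' correction, floored at `dispersion_floor`. The Wald statistic is the
#' condition coefficient over its standard error with a two-sided normal
#' p-value; p-values are BH-adjusted and miRNAs are flagged significant at
#' `adj_p < alpha` with no fold-change criterion.
#'
#' @inheritParams count_matrix
#' @param condition Two-level factor/vector over samples; the fold change is
#'   level 2 relative to level 1.
#' @param alpha Adjusted-p significance threshold, default 0.1.
#' @param size_factors Optional named size factors; estimated when `NULL`.
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return A `uromir_de` tibble: `mirna`, `base_mean`, `log2_fold_change`,
#'   `wald_stat`, `p_value`, `adj_p`, `significant`, `degenerate`.
#' @export
nb_wald_de <- function(counts, condition, alpha = 0.1, size_factors = NULL,
                       dispersion_floor = 1e-8) {
  m <- count_matrix(counts)
  condition <- as.factor(condition)
  if (length(condition) != ncol(m)) abort("`condition` must have one label per sample.")
  if (nlevels(condition) != 2 || any(table(condition) == 0)) {
    abort("`condition` must have exactly two non-empty levels.")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors[colnames(m)]
  off <- log(sf)
  cond01 <- as.integer(condition) - 1L
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    nb_wald_one(m[i, ], cond01, off, sf, dispersion_floor)
  })
  out <- dplyr::bind_cols(tibble(mirna = rownames(m)), dplyr::bind_rows(res))
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- out$adj_p < alpha
  class(out) <- c("uromir_de", class(out))
  attr(out, "alpha") <- alpha
  out
}

nb_wald_one <- function(y, cond01, off, sf, floor) {
  base_mean <- mean(y / sf)
  if (all(y == 0)) {
    return(tibble(base_mean = 0, log2_fold_change = 0, wald_stat = 0,
                  p_value = 1, degenerate = TRUE))
  }
  disp <- mom_dispersion(y, cond01, sf, floor)
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      y ~ cond01 + offset(off),
      family = MASS::negative.binomial(theta = 1 / disp))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || is.na(stats::coef(fit)[2])) {
    return(tibble(base_mean = base_mean, log2_fold_change = 0, wald_stat = 0,
                  p_value = 1, degenerate = TRUE))
  }
  co <- summary(fit, dispersion = 1)$coefficients
  z <- co[2, 1] / co[2, 2]
  tibble(base_mean = base_mean,
         log2_fold_change = co[2, 1] / log(2),
         wald_stat = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         degenerate = FALSE)
}

# pooled within-group moment estimator of the NB dispersion on
# size-factor-normalized counts, with an n/(n-1) small-sample factor
mom_dispersion <- function(y, cond01, sf, floor) {
  z <- y / sf
  ests <- vapply(split(seq_along(y), cond01), function(idx) {
    zz <- z[idx]; n <- length(zz); mu <- mean(zz)
    if (n < 2 || mu == 0) return(c(NA_real_, 0))
    a <- (stats::var(zz) - mu * mean(1 / sf[idx])) / mu^2
    c(a * n / (n - 1), n - 1)
  }, numeric(2))
  w <- ests[2, ]
  a <- ests[1, ]
  ok <- !is.na(a) & w > 0
  pooled <- if (any(ok)) sum(a[ok] * w[ok]) / sum(w[ok]) else floor
  min(10, max(floor, pooled))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1, input order
#' preserved), with input validation.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must all lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman stage-trend test per miRNA
#'
#' Correlates CPM values with an ordinal stage coding: HR = 0, stage I = 1,
#' II = 2, III = 3, IV = 4 (substages IA/IB and IIA/IIB merged by default).
#' Stage-0 samples are excluded. Midrank ties, asymptotic p-values.
#'
#' @param cpm Wide CPM tibble (from [cpm_normalize()]).
#' @param meta Sample metadata with `sample_id`, `cohort`, `stage`.
#' @param merge_substages Merge IA/IB into I and IIA/IIB into II (default
#'   `TRUE`); otherwise substages get half-step codes.
#' @return A `uromir_trend` tibble: `mirna`, `spearman_rho`, `p_value`,
#'   `degenerate`; the stage coding used is in `attr(, "stage_coding")`.
#' @export
spearman_stage_trend <- function(cpm, meta, merge_substages = TRUE) {
  m <- count_matrix(cpm)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  coding <- if (merge_substages) {
    c(HR = 0, IA = 1, IB = 1, IIA = 2, IIB = 2, III = 3, IV = 4)
  } else {
    c(HR = 0, IA = 1, IB = 1.5, IIA = 2, IIB = 2.5, III = 3, IV = 4)
  }
  key <- ifelse(meta$cohort == "HR", "HR", meta$stage)
  stage_num <- unname(coding[key])
  use <- !is.na(stage_num)   # drops stage 0, general population, other arms
  if (sum(use) < 3) abort("fewer than 3 usable samples after stage exclusions.")
  x <- stage_num[use]
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, use]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(tibble(spearman_rho = 0, p_value = 1, degenerate = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    tibble(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
           degenerate = FALSE)
  })
  out <- dplyr::bind_cols(tibble(mirna = rownames(m)), dplyr::bind_rows(res))
  class(out) <- c("uromir_trend", class(out))
  attr(out, "stage_coding") <- coding
  out
}
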