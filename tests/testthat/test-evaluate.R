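test_that("AUC equals the pairwise-comparison oracle and honours ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(14)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # rounding forces ties
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(y, s), mean(pairs))
  }

  # invariance under strictly increasing transforms
  y <- rbinom(50, 1, 0.4); y[1:2] <- c(0, 1)
  s <- runif(50)
  expect_equal(roc_auc(y, s), roc_auc(y, qlogis(s)))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- c(0, 1, rbinom(38, 1, 0.5))
  s <- round(runif(40), 2)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(roc_auc(y, s), ref)
})

test_that("confusion metrics reproduce the hold-out operating point", {
  expect_equal(confusion_at_threshold(c(1, 1, 0), c(0.2, 0.9, 0.1), 0)$sensitivity, 1)
  cm0 <- confusion_at_threshold(c(1, 1, 0), c(0.2, 0.9, 0.1), 0.95)
  expect_equal(cm0$sensitivity, 0)
  expect_equal(cm0$specificity, 1)

  # 30 positives with 24 above threshold, 19 negatives with 15 below
  y <- c(rep(1, 30), rep(0, 19))
  s <- c(rep(0.9, 24), rep(0.1, 6), rep(0.1, 15), rep(0.9, 4))
  cm <- confusion_at_threshold(y, s, 0.5)
  expect_equal(cm$sensitivity, 0.800)
  expect_equal(round(cm$specificity, 3), 0.789)
  expect_equal(cm$tp + cm$fn, 30)
  expect_equal(cm$tn + cm$fp, 19)
})

test_that("Wilson intervals match the published operating-point CIs", {
  expect_equal(unname(round(wilson_ci(24, 30), 3)), c(0.627, 0.905))
  expect_equal(unname(round(wilson_ci(15, 19), 3)), c(0.567, 0.915))
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  w <- wilson_ci(7, 9)
  expect_true(w["lower"] <= 7 / 9 && 7 / 9 <= w["upper"])
  expect_error(wilson_ci(5, 0), "n >= 1")
})

test_that("t-based fold CIs match the published cross-validation CIs", {
  # any 10 values with the printed mean and sd give the printed interval
  make_vals <- function(m, s, k = 10) {
    v <- scale(seq_len(k))[, 1]
    m + s * v / stats::sd(v)
  }
  ci1 <- t_mean_ci(make_vals(0.798, 0.120))
  expect_equal(unname(round(ci1[c("lower", "upper")], 3)), c(0.712, 0.884))
  ci2 <- t_mean_ci(make_vals(0.800, 0.126))
  expect_equal(unname(round(ci2[c("lower", "upper")], 3)), c(0.710, 0.890))

  cc <- t_mean_ci(rep(0.5, 6))
  expect_equal(unname(cc[c("mean", "lower", "upper")]), c(0.5, 0.5, 0.5))
  expect_error(t_mean_ci(0.7), "2 fold values")
})

test_that("predictive values follow the prevalence arithmetic", {
  pv <- ppv_npv(0.80, 0.80, 0.01)
  expect_equal(round(pv$ppv, 3), 0.039)
  expect_equal(round(pv$npv, 3), 0.997)

  perfect <- ppv_npv(1, 1, 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  zero <- ppv_npv(0.9, 1, 0)
  expect_true(is.na(zero$ppv))
  expect_equal(zero$npv, 1)
  expect_equal(zero$flag, "ppv_undefined")

  # total-probability identity
  s <- 0.7; cc <- 0.85; pi <- 0.2
  expect_equal(pi * s + pi * (1 - s) + (1 - pi) * cc + (1 - pi) * (1 - cc), 1)
})

test_that("stage-stratified sensitivity splits early 0-IIA from late IIB-IV", {
  meta <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:30),
    stage = c(rep("0", 1), rep("IA", 4), rep("IB", 3), rep("IIA", 3),
              rep("IIB", 6), rep("III", 6), rep("IV", 7)))
  scores <- tibble::tibble(sample_id = meta$sample_id,
                           score = rep(1, 30))
  all_hit <- stage_stratified_sensitivity(meta, scores, 0.5)
  expect_equal(all_hit$sensitivity[all_hit$group == "early"], 1)

  # 8/11 early and 16/19 late detected -> 0.727 / 0.842
  scores$score <- 0
  early_ids <- meta$sample_id[meta$stage %in% c("0", "IA", "IB", "IIA")]
  late_ids <- setdiff(meta$sample_id, early_ids)
  scores$score[scores$sample_id %in% early_ids[1:8]] <- 1
  scores$score[scores$sample_id %in% late_ids[1:16]] <- 1
  res <- stage_stratified_sensitivity(meta, scores, 0.5)
  expect_equal(round(res$sensitivity[res$group == "early"], 3), 0.727)
  expect_equal(round(res$sensitivity[res$group == "late"], 3), 0.842)
  # printed late-stage hold-out CI is Clopper-Pearson
  expect_equal(round(res$cp_lower[res$group == "late"], 3), 0.604)
  expect_equal(round(res$cp_upper[res$group == "late"], 3), 0.966)

  # count-weighted stage sensitivities recompose the overall sensitivity
  e <- res[res$group == "early", ]; l <- res[res$group == "late", ]
  overall <- (e$detected + l$detected) / (e$n + l$n)
  expect_equal(overall, 24 / 30)
})

test_that("CA19-9 classification applies the strict 37 U/mL rule", {
  vals <- c(37.0, 37.1, 100, 5, NA, 40)
  labs <- c(1, 1, 1, 0, 1, 0)
  res <- ca199_classify(vals, labs)
  # 37.0 is negative (not exceeding), 37.1 positive
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$specificity, 1 / 2)
  expect_equal(res$n_used, 5)
  expect_equal(res$n_missing, 1)
  expect_error(ca199_classify(c(-1, 5), c(0, 1)), "negative")

  # counting oracle on a simulated cohort
  co <- simulate_cohort_counts(two_group_design(n_pdac = 80, n_hr = 80,
                                                n_mirnas = 5,
                                                n_informative = 0,
                                                seed = 55))
  y <- as.numeric(co$meta$cohort == "PDAC")
  got <- ca199_classify(co$meta$ca19_9, y)
  use <- !is.na(co$meta$ca19_9)
  expect_equal(got$sensitivity,
               mean(co$meta$ca19_9[use & y == 1] > 37))
  expect_equal(got$specificity,
               mean(co$meta$ca19_9[use & y == 0] <= 37))
})

test_that("subgroup association picks the method by covariate type", {
  set.seed(16)
  scores <- runif(200)
  self <- subgroup_association(scores, scores)
  expect_equal(self$method, "pearson")
  expect_equal(self$statistic, 1)

  indep <- subgroup_association(scores, rnorm(200))
  expect_lt(abs(indep$statistic), 0.2)
  expect_gt(indep$p_value, 0.001)

  binres <- subgroup_association(scores, rep(c("a", "b"), 100))
  expect_equal(binres$method, "wilcoxon")
  multi <- subgroup_association(scores, rep(c("a", "b", "c", "d"), 50))
  expect_equal(multi$method, "kruskal-wallis")

  const <- subgroup_association(scores, rep("x", 200))
  expect_equal(const$p_value, 1)
  expect_error(subgroup_association(c(1, 2), c(1, 2)), "3 non-missing")
})

test_that("rank-sum p-values are calibrated under identical distributions", {
  set.seed(17)
  ps <- replicate(200, {
    s <- rnorm(40)
    subgroup_association(s, rep(c("a", "b"), 20))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("evaluate_classifier assembles a coherent report", {
  d <- two_group_design(n_pdac = 40, n_hr = 40, n_mirnas = 50,
                        n_informative = 6, lfc = 1.5, seed = 57)
  co <- simulate_cohort_counts(d)
  sub <- pdac_hr_subset(co)
  b <- train_classifier(sub$counts, sub$meta, n_iter = 30, k = 5,
                        max_features = 8, search_budget = 3, seed = 4)
  ev <- evaluate_classifier(b, sub$counts, sub$meta, prevalence = 0.01)
  expect_gte(ev$auc, 0.5)
  expect_true(ev$sensitivity_ci["lower"] <= ev$sensitivity)
  expect_true(ev$sensitivity <= ev$sensitivity_ci["upper"])
  expect_equal(nrow(ev$cv_summary), 3)
  expect_true(all(c("early", "late") %in% ev$stage_sensitivity$group))
  expect_true(is.numeric(ev$ppv) && is.numeric(ev$npv))
  expect_true("ca19_9" %in% ev$subgroup_associations$covariate)

  td <- tidy(ev)
  expect_true(all(c("auc", "sensitivity", "specificity") %in% td$metric))
  g <- glance(ev)
  expect_equal(g$auc, ev$auc)
})

test_that("tidiers and autoplot methods return well-formed objects", {
  d <- two_group_design(n_pdac = 25, n_hr = 25, n_mirnas = 40,
                        n_informative = 5, lfc = 1.5, seed = 58)
  co <- simulate_cohort_counts(d)
  de <- nb_wald_de(co$counts, co$meta$cohort == "PDAC")
  expect_s3_class(autoplot(de), "ggplot")
  gl <- glance(de)
  expect_equal(gl$n_mirnas, 40)
  expect_equal(gl$n_significant, sum(de$significant))

  sub <- pdac_hr_subset(co)
  b <- train_classifier(sub$counts, sub$meta, n_iter = 20, k = 5,
                        max_features = 5, search_budget = 2, seed = 5)
  expect_s3_class(autoplot(b$ranking), "ggplot")
  expect_true(all(tidy(b)$feature %in% b$features))
  expect_equal(glance(b)$n_features, length(b$features))
  p <- plot_roc(sub$meta$cohort == "PDAC",
                predict(b, sub$counts, sub$meta)$score)
  expect_s3_class(p, "ggplot")
})
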