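# Machine-learning procedure for detecting PDAC against high-risk controls:
# balance-checked 80/20 split, bootstrap feature-importance ranking with a
# gradient-boosted tree learner (xgboost, binary log-loss), forward
# selection by 10-fold cross-validated AUC, randomized log-loss tuning, and
# calibration of the score threshold to a target training sensitivity.

#' Age/sex-stratified train/hold-out split with balance selection
#'
#' For every candidate seed an age/sex-stratified random split is drawn
#' (strata: cohort x sex x within-cohort age tertile). The adopted split
#' minimizes a balance score: the sum over PDAC stage categories and HR
#' risk-factor categories of |train proportion - hold-out proportion|.
#' Deterministic given `candidate_seeds`; ties keep the earliest seed.
#'
#' @param meta Sample metadata (`sample_id`, `cohort`, `stage`, `age`,
#'   `sex`, `risk_factors`).
#' @param train_fraction Fraction of samples assigned to training.
#' @param candidate_seeds Integer seeds to try (non-empty).
#' @return A `uromir_split` list: `train_ids`, `holdout_ids`, `chosen_seed`,
#'   `balance_score`, `balance_report` (per-side stage / risk-factor / age /
#'   sex summaries).
#' @export
stratified_split <- function(meta, train_fraction = 0.8,
                             candidate_seeds = 1:20) {
  if (length(candidate_seeds) == 0) abort("`candidate_seeds` must be non-empty.")
  if (any(table(meta$cohort) < 2)) abort("need >= 2 samples per cohort.")
  trials <- purrr::map(candidate_seeds, function(s) {
    train <- with_rng(s, draw_stratified(meta, train_fraction))
    list(seed = s, train = train,
         score = split_balance_score(meta, train))
  })
  best <- trials[[which.min(purrr::map_dbl(trials, "score"))]]
  train_ids <- meta$sample_id[best$train]
  holdout_ids <- setdiff(meta$sample_id, train_ids)
  structure(list(
    train_ids = train_ids, holdout_ids = holdout_ids,
    chosen_seed = best$seed, balance_score = best$score,
    balance_report = split_balance_report(meta, train_ids)),
    class = "uromir_split")
}

draw_stratified <- function(meta, train_fraction) {
  age_bin <- stats::ave(meta$age, meta$cohort, FUN = function(a) {
    br <- unique(stats::quantile(a, c(0, 1/3, 2/3, 1)))
    if (length(br) < 2) rep(1, length(a)) else as.integer(cut(a, br, include.lowest = TRUE))
  })
  strata <- interaction(meta$cohort, meta$sex, age_bin, drop = TRUE)
  in_train <- logical(nrow(meta))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    n_tr <- round(train_fraction * length(idx))
    in_train[sample(idx, n_tr)] <- TRUE
  }
  in_train
}

split_balance_score <- function(meta, in_train) {
  if (is.character(in_train)) in_train <- meta$sample_id %in% in_train
  prop_gap <- function(cat_tbl) {
    cats <- unique(cat_tbl$cat)
    tr <- cat_tbl$cat[cat_tbl$train]; ho <- cat_tbl$cat[!cat_tbl$train]
    if (length(tr) == 0 || length(ho) == 0) return(Inf)
    sum(abs(vapply(cats, function(cc) mean(tr == cc) - mean(ho == cc),
                   numeric(1))))
  }
  pdac <- meta$cohort == "PDAC"
  hr <- meta$cohort == "HR"
  gap <- 0
  if (any(pdac)) {
    gap <- gap + prop_gap(tibble(cat = meta$stage[pdac], train = in_train[pdac]))
  }
  if (any(hr) && "risk_factors" %in% names(meta)) {
    rf <- strsplit(ifelse(is.na(meta$risk_factors[hr]), "", meta$risk_factors[hr]), ";")
    tr_hr <- in_train[hr]
    for (f in unique(unlist(rf))) {
      has <- vapply(rf, function(v) f %in% v, logical(1))
      gap <- gap + abs(mean(has[tr_hr]) - mean(has[!tr_hr]))
    }
  }
  gap
}

split_balance_report <- function(meta, train_ids) {
  side <- ifelse(meta$sample_id %in% train_ids, "train", "holdout")
  meta %>%
    dplyr::mutate(side = side) %>%
    dplyr::group_by(.data$side, .data$cohort) %>%
    dplyr::summarise(n = dplyr::n(), age_mean = mean(.data$age),
                     age_sd = stats::sd(.data$age),
                     frac_male = mean(.data$sex == "M"), .groups = "drop")
}

#' Assemble the classifier feature table
#'
#' Features are CPM-normalized miRNA expression plus sex (M = 1, F = 0) and
#' age in years, untransformed. CPM is computed per sample against `totals`
#' (defaulting to each sample's own column total), so new samples can be
#' normalized independently.
#'
#' @inheritParams count_matrix
#' @param meta Sample metadata covering the count columns.
#' @param totals Optional per-sample totals for CPM (e.g. totals over all
#'   quantified miRNAs before prevalence filtering).
#' @param mirnas Optional required miRNA set; missing ones raise an error
#'   naming them.
#' @return Tibble: `sample_id`, one column per miRNA, `sex`, `age`.
#' @export
build_feature_table <- function(counts, meta, totals = NULL, mirnas = NULL) {
  if (!is.null(mirnas)) {
    missing <- setdiff(mirnas, counts$mirna)
    if (length(missing) > 0) {
      abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
    }
    counts <- counts[counts$mirna %in% mirnas, ]
  }
  cpm <- cpm_normalize(counts, totals)
  x <- t(count_matrix(cpm))
  meta <- meta[match(rownames(x), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) abort("`meta` must cover every count column.")
  dplyr::bind_cols(tibble(sample_id = rownames(x)), as_tibble(x),
                   tibble(sex = as.numeric(meta$sex == "M"), age = as.numeric(meta$age)))
}

feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- as.matrix(x[, setdiff(names(x), c("sample_id", "label")), drop = FALSE])
  rownames(m) <- if ("sample_id" %in% names(x)) x$sample_id else NULL
  m
}

# stratified k-fold assignment drawn from the current RNG stream
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# weak additive expression differences at n ~ 200 favour shallow trees and
# slow learning; depth-2/eta-0.05 is the package's untuned reference config
default_gbt_params <- function() {
  list(objective = "binary:logistic", max_depth = 2, eta = 0.05,
       min_child_weight = 2, subsample = 1, colsample_bytree = 1,
       lambda = 1, nthread = 1, verbosity = 0, seed = 20260101)
}

fit_gbt <- function(x, y, params, nrounds) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds)
}

gbt_cv_scores <- function(x, y, folds, params, nrounds) {
  oof <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fit_gbt(x[tr, , drop = FALSE], y[tr], params, nrounds)
    oof[!tr] <- stats::predict(model, xgboost::xgb.DMatrix(
      x[!tr, , drop = FALSE], nthread = 1))
  }
  oof
}

#' Bootstrap feature-importance ranking
#'
#' Repeats `n_iter` times: sample `ceiling(subset_fraction * p)` features
#' without replacement, run k-fold cross-validation of the boosted-tree
#' learner on that subset (folds redrawn each iteration), and accumulate
#' each feature's total-gain importance. A feature's mean importance is its
#' accumulated gain divided by the number of iterations in which it was
#' sampled; ranking is by descending mean importance, never-sampled features
#' last (with a warning).
#'
#' @param x Feature tibble/matrix (numeric columns; `sample_id` ignored).
#' @param y Binary labels (0/1).
#' @param n_iter Number of bootstrap iterations (study-scale value 50,000;
#'   package default 500).
#' @param subset_fraction Fraction of features sampled per iteration.
#' @param k Cross-validation folds per iteration.
#' @param seed Integer seed; the whole procedure is deterministic under it.
#' @param params,nrounds Learner parameters for the ranking fits.
#' @return A `uromir_ranking` tibble: `feature`, `mean_importance`,
#'   `times_sampled`, `rank`.
#' @export
bootstrap_feature_ranking <- function(x, y, n_iter = 500,
                                      subset_fraction = 0.3, k = 10,
                                      seed = 1, params = NULL, nrounds = 15) {
  stopifnot(n_iter >= 1)
  x <- feature_matrix(x)
  p <- ncol(x)
  if (is.null(params)) {
    params <- utils::modifyList(default_gbt_params(), list(eta = 0.3))
  }
  n_sub <- max(1L, ceiling(subset_fraction * p))
  gain_sum <- stats::setNames(numeric(p), colnames(x))
  times <- stats::setNames(integer(p), colnames(x))
  with_rng(seed, {
    for (it in seq_len(n_iter)) {
      feats <- sample.int(p, n_sub)
      folds <- make_folds(y, k)
      g <- stats::setNames(numeric(n_sub), colnames(x)[feats])
      for (f in seq_len(k)) {
        tr <- folds != f
        model <- fit_gbt(x[tr, feats, drop = FALSE], y[tr], params, nrounds)
        # a booster whose trees never split has no importance to report
        imp <- tryCatch(xgboost::xgb.importance(model = model),
                        error = function(e) NULL)
        if (!is.null(imp) && nrow(imp) > 0) {
          g[imp$Feature] <- g[imp$Feature] + imp$Gain
        }
      }
      gain_sum[feats] <- gain_sum[feats] + g / k
      times[feats] <- times[feats] + 1L
      # release accumulated booster/DMatrix handles promptly
      if (it %% 25 == 0) gc(verbose = FALSE)
    }
  })
  never <- names(times)[times == 0]
  if (length(never) > 0) {
    warn(paste0("feature(s) never sampled across iterations (ranked last): ",
                paste(never, collapse = ", ")))
  }
  mean_imp <- ifelse(times > 0, gain_sum / pmax(times, 1L), NA_real_)
  ord <- order(-ifelse(is.na(mean_imp), -Inf, mean_imp))
  out <- tibble(feature = colnames(x)[ord],
                mean_importance = mean_imp[ord],
                times_sampled = as.integer(times[ord]),
                rank = seq_len(p))
  class(out) <- c("uromir_ranking", class(out))
  out
}

#' Forward feature selection by cross-validated AUC
#'
#' Evaluates ranking prefixes of size 1..`max_features` by k-fold CV AUC
#' with one fixed fold assignment across all prefix sizes, and returns the
#' prefix with maximal mean AUC (smallest prefix on ties).
#'
#' @param ranking A [bootstrap_feature_ranking()] result covering `x`.
#' @inheritParams bootstrap_feature_ranking
#' @param max_features Largest prefix size evaluated.
#' @return A `uromir_selection` list: `features`, `cv_auc`, `auc_path`
#'   (tibble `n_features`, `cv_auc`), `folds`.
#' @export
forward_select <- function(ranking, x, y, k = 10, max_features = 30,
                           seed = 1, params = NULL, nrounds = 150) {
  if (max_features < 1) abort("`max_features` must be >= 1.")
  x <- feature_matrix(x)
  if (!all(colnames(x) %in% ranking$feature)) {
    abort("`ranking` must cover every column of `x`.")
  }
  if (is.null(params)) params <- default_gbt_params()
  max_features <- min(max_features, ncol(x))
  folds <- with_rng(seed, make_folds(y, k))
  path <- vapply(seq_len(max_features), function(s) {
    feats <- ranking$feature[seq_len(s)]
    oof <- gbt_cv_scores(x[, feats, drop = FALSE], y, folds, params, nrounds)
    roc_auc(y, oof)
  }, numeric(1))
  best <- which.max(path)   # first maximum = smallest prefix on ties
  structure(list(
    features = ranking$feature[seq_len(best)],
    cv_auc = path[best],
    auc_path = tibble(n_features = seq_len(max_features), cv_auc = path),
    folds = folds, params = params, nrounds = nrounds),
    class = "uromir_selection")
}

#' Randomized hyperparameter search and final fit
#'
#' Scores boosted-tree configurations by k-fold CV log loss on the selected
#' features, then refits the best configuration on the whole training set.
#' The first candidates are three fixed anchors spanning the
#' depth/learning-rate trade-off (stumps at eta 0.03 x 600 rounds, depth 2
#' at eta 0.05 x 300, depth 3 at eta 0.1 x 150); the remaining budget is
#' random draws from: `nrounds` 100-600, `max_depth` 1-4, `eta`
#' 10^U(-1.8, -0.7), `min_child_weight` 1-10, `subsample` U(0.6, 1),
#' `colsample_bytree` U(0.5, 1), `lambda` 10^U(-2, 1).
#'
#' @inheritParams bootstrap_feature_ranking
#' @param features Selected feature names (subset of `x` columns).
#' @param search_budget Number of configurations evaluated (>= 1).
#' @param folds Optional fixed fold assignment; drawn from `seed` if `NULL`.
#' @return A `uromir_fit` list: `model_raw` (serialized booster), `params`,
#'   `nrounds`, `cv_logloss`, `oof_scores`, `folds`, `search` (tibble of all
#'   configurations and losses).
#' @export
tune_and_train <- function(x, y, features, search_budget = 20, k = 10,
                           seed = 1, folds = NULL) {
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  stopifnot(search_budget >= 1)
  x <- feature_matrix(x)
  missing <- setdiff(features, colnames(x))
  if (length(missing) > 0) {
    abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  xf <- x[, features, drop = FALSE]
  with_rng(seed, {
    if (is.null(folds)) folds <- make_folds(y, k)
    anchors <- list(
      list(params = utils::modifyList(default_gbt_params(),
                                      list(max_depth = 1, eta = 0.03)),
           nrounds = 600),
      list(params = default_gbt_params(), nrounds = 300),
      list(params = utils::modifyList(default_gbt_params(),
                                      list(max_depth = 3, eta = 0.1)),
           nrounds = 150))
    configs <- anchors[seq_len(min(search_budget, length(anchors)))]
    while (length(configs) < search_budget) {
      configs[[length(configs) + 1]] <- list(
        params = utils::modifyList(default_gbt_params(), list(
          max_depth = sample(1:4, 1),
          eta = 10^stats::runif(1, -1.8, -0.7),
          min_child_weight = sample(1:10, 1),
          subsample = stats::runif(1, 0.6, 1),
          colsample_bytree = stats::runif(1, 0.5, 1),
          lambda = 10^stats::runif(1, -2, 1))),
        nrounds = sample(100:600, 1))
    }
    losses <- numeric(length(configs))
    oofs <- vector("list", length(configs))
    for (i in seq_along(configs)) {
      oofs[[i]] <- gbt_cv_scores(xf, y, folds, configs[[i]]$params,
                                 configs[[i]]$nrounds)
      losses[i] <- log_loss(y, oofs[[i]])
    }
    best <- which.min(losses)
    model <- fit_gbt(xf, y, configs[[best]]$params, configs[[best]]$nrounds)
    structure(list(
      model_raw = xgboost::xgb.save.raw(model),
      features = features,
      params = configs[[best]]$params, nrounds = configs[[best]]$nrounds,
      cv_logloss = losses[best], oof_scores = oofs[[best]], folds = folds,
      search = tibble(config = seq_along(configs), logloss = losses)),
      class = "uromir_fit")
  })
}

log_loss <- function(y, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Calibrate the score threshold to a target sensitivity
#'
#' Returns the largest score cutoff whose out-of-fold sensitivity (positive
#' call = score >= threshold) is at least `target_sensitivity`, together
#' with the sensitivity actually achieved.
#'
#' @param scores Out-of-fold prediction scores in [0, 1].
#' @param y Binary labels (1 = positive class).
#' @param target_sensitivity Target training sensitivity, default 0.8.
#' @return List with `threshold` and `achieved_sensitivity`.
#' @export
calibrate_threshold <- function(scores, y, target_sensitivity = 0.8) {
  pos <- scores[y == 1]
  if (length(pos) == 0) abort("no positive samples to calibrate against.")
  cands <- sort(unique(pos), decreasing = TRUE)
  sens <- vapply(cands, function(cc) mean(pos >= cc), numeric(1))
  ok <- which(sens >= target_sensitivity)
  if (length(ok) == 0) {
    warn("target sensitivity unachievable; using the minimum score.")
    return(list(threshold = min(scores), achieved_sensitivity = 1))
  }
  i <- ok[1]
  list(threshold = cands[i], achieved_sensitivity = sens[i])
}

#' Train the full PDAC-vs-HR classifier
#'
#' End-to-end training procedure on a count table and metadata restricted
#' to the training samples: prevalence filter (>= 2 counts in more than
#' `prevalence_fraction` of samples), CPM normalization against totals over
#' all quantified miRNAs, feature table (miRNA CPM + sex + age), bootstrap
#' importance ranking, forward selection by CV AUC, randomized log-loss
#' tuning, and threshold calibration to the target sensitivity on
#' out-of-fold scores. Deterministic under `seed`.
#'
#' @inheritParams build_feature_table
#' @param positive,negative Cohort labels of the two classes.
#' @param prevalence_fraction Prevalence-filter fraction for the ML stage.
#' @param target_sensitivity Training sensitivity target for the threshold.
#' @inheritParams bootstrap_feature_ranking
#' @inheritParams tune_and_train
#' @param max_features Largest forward-selection prefix evaluated.
#' @param learner `"gbt"` (gradient-boosted trees) or `"logistic"`
#'   (untuned logistic-regression baseline).
#' @return A `uromir_classifier` bundle: `features`, serialized model,
#'   hyperparameters, `threshold`, `cv_fold_metrics`, `ranking`, `auc_path`.
#' @export
train_classifier <- function(counts, meta, totals = NULL,
                             positive = "PDAC", negative = "HR",
                             prevalence_fraction = 0.8,
                             target_sensitivity = 0.8,
                             n_iter = 500, subset_fraction = 0.3, k = 10,
                             max_features = 30, search_budget = 20,
                             learner = c("gbt", "logistic"), seed = 1) {
  learner <- match.arg(learner)
  keep <- meta$sample_id[meta$cohort %in% c(positive, negative)]
  keep <- intersect(names(counts), keep)
  counts <- counts[, c("mirna", keep)]
  meta <- meta[match(keep, meta$sample_id), ]
  if (is.null(totals)) totals <- count_totals(counts)
  filtered <- prevalence_filter(counts, 2, prevalence_fraction)
  ft <- build_feature_table(filtered, meta, totals = totals)
  x <- feature_matrix(ft)
  y <- as.numeric(meta$cohort == positive)
  ranking <- bootstrap_feature_ranking(x, y, n_iter = n_iter,
                                       subset_fraction = subset_fraction,
                                       k = k, seed = seed)
  sel <- forward_select(ranking, x, y, k = k, max_features = max_features,
                        seed = seed + 1L)
  # tuning redraws its own folds so the configuration choice is not scored
  # on the exact partition the feature set was selected on
  if (learner == "gbt") {
    fit <- tune_and_train(x, y, sel$features, search_budget = search_budget,
                          k = k, seed = seed + 2L)
    oof <- fit$oof_scores
  } else {
    fit <- logistic_fit(x, y, sel$features, sel$folds)
    oof <- fit$oof_scores
  }
  cal <- calibrate_threshold(oof, y, target_sensitivity)
  cv_folds <- if (learner == "gbt") fit$folds else sel$folds
  fold_metrics <- purrr::map_dfr(sort(unique(cv_folds)), function(f) {
    idx <- cv_folds == f
    cm <- confusion_at_threshold(y[idx], oof[idx], cal$threshold)
    tibble(fold = f,
           auc = tryCatch(roc_auc(y[idx], oof[idx]), error = function(e) NA_real_),
           sensitivity = cm$sensitivity, specificity = cm$specificity)
  })
  structure(list(
    learner = learner,
    features = sel$features,
    mirna_features = setdiff(sel$features, c("sex", "age")),
    fit = fit,
    threshold = cal$threshold,
    achieved_sensitivity = cal$achieved_sensitivity,
    target_sensitivity = target_sensitivity,
    cv_fold_metrics = fold_metrics,
    oof_scores = tibble(sample_id = meta$sample_id, label = y, score = oof),
    ranking = ranking, auc_path = sel$auc_path,
    positive = positive, negative = negative, seed = seed),
    class = "uromir_classifier")
}

logistic_fit <- function(x, y, features, folds) {
  xf <- as.data.frame(x[, features, drop = FALSE])
  oof <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- suppressWarnings(stats::glm(y[tr] ~ ., data = xf[tr, , drop = FALSE],
                                       family = stats::binomial()))
    oof[!tr] <- stats::predict(fit, xf[!tr, , drop = FALSE], type = "response")
  }
  final <- suppressWarnings(stats::glm(y ~ ., data = xf, family = stats::binomial()))
  structure(list(coefficients = stats::coef(final), features = features,
                 oof_scores = oof, folds = folds, cv_logloss = log_loss(y, oof)),
            class = "uromir_logistic_fit")
}

#' Score new samples with a trained classifier bundle
#'
#' Missing feature columns (miRNAs absent from `counts`) raise an error
#' naming them. Positive call = score >= the bundle's calibrated threshold.
#'
#' @param object A `uromir_classifier` from [train_classifier()].
#' @param counts Wide count tibble for the new samples.
#' @param meta Metadata covering the new samples (`sample_id`, `age`, `sex`).
#' @param totals Optional per-sample CPM totals (defaults to each sample's
#'   own total over the supplied counts).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `score`, `call` (logical).
#' @export
predict.uromir_classifier <- function(object, counts, meta, totals = NULL, ...) {
  if (is.null(totals)) totals <- count_totals(counts)
  ft <- build_feature_table(counts, meta, totals = totals,
                            mirnas = object$mirna_features)
  x <- feature_matrix(ft)[, object$features, drop = FALSE]
  scores <- if (object$learner == "gbt") {
    model <- xgboost::xgb.load.raw(object$fit$model_raw)
    stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  } else {
    co <- object$fit$coefficients
    stats::plogis(co[1] + as.numeric(x %*% co[-1]))
  }
  tibble(sample_id = ft$sample_id, score = as.numeric(scores),
         call = scores >= object$threshold)
}

#' @export
print.uromir_classifier <- function(x, ...) {
  cat("PDAC classifier (", x$learner, ")\n", sep = "")
  cat("  features: ", length(x$features), " (",
      paste(utils::head(x$features, 5), collapse = ", "),
      if (length(x$features) > 5) ", ..." else "", ")\n", sep = "")
  cat(sprintf("  threshold: %.3f (target sensitivity %.2f, achieved %.3f)\n",
              x$threshold, x$target_sensitivity, x$achieved_sensitivity))
  cat(sprintf("  CV AUC (mean over folds): %.3f\n",
              mean(x$cv_fold_metrics$auc, na.rm = TRUE)))
  invisible(x)
}
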