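# Full-pipeline helper used by the end-to-end suites: simulate a cohort at
# the default study conditions, QC-filter, split 80/20, train at the given
# bootstrap budget, evaluate the hold-out, and report AUCs next to the
# likelihood-ratio oracle.

run_cohort_pipeline <- function(seed, n_iter = 500, design = cohort_design(seed = seed)) {
  co <- simulate_cohort_counts(design)
  qcf <- qc_filter_samples(co$counts)
  meta <- co$meta[co$meta$sample_id %in% names(qcf$counts) &
                    co$meta$cohort %in% c("PDAC", "HR"), ]
  counts <- qcf$counts[, c("mirna", meta$sample_id)]
  sp <- stratified_split(meta, 0.8, candidate_seeds = 1:10)
  tr_meta <- meta[meta$sample_id %in% sp$train_ids, ]
  ho_meta <- meta[meta$sample_id %in% sp$holdout_ids, ]
  bundle <- train_classifier(counts[, c("mirna", sp$train_ids)], tr_meta,
                             n_iter = n_iter, seed = seed)
  ev <- evaluate_classifier(bundle, counts[, c("mirna", sp$holdout_ids)],
                            ho_meta)
  os <- oracle_scores(co, counts)
  oracle_full <- roc_auc(meta$cohort == "PDAC",
                         os$oracle_score[match(meta$sample_id, os$sample_id)])
  oracle_holdout <- roc_auc(
    ho_meta$cohort == "PDAC",
    os$oracle_score[match(sp$holdout_ids, os$sample_id)])
  selected_mirnas <- bundle$mirna_features
  n_planted_selected <- sum(selected_mirnas %in% co$truth$informative)
  enrichment_p <- stats::phyper(
    n_planted_selected - 1, length(co$truth$informative),
    nrow(counts) - length(co$truth$informative),
    length(selected_mirnas), lower.tail = FALSE)
  list(holdout_auc = ev$auc, oracle_auc = oracle_full,
       oracle_holdout_auc = oracle_holdout,
       holdout_sensitivity = ev$sensitivity,
       holdout_specificity = ev$specificity,
       n_features = length(bundle$features),
       n_planted_selected = n_planted_selected,
       n_selected_mirnas = length(selected_mirnas),
       enrichment_p = enrichment_p,
       threshold = bundle$threshold)
}

# Run `fn(...)` in a forked child, retrying on an abnormal child exit.
# xgboost shows very rare heap corruption in extremely long fit loops; the
# computation is deterministic under its seed, so a retry reproduces the
# same value. Falls back to in-process evaluation where forking is
# unavailable.
run_isolated <- function(fn, ..., retries = 2) {
  if (.Platform$OS.type != "unix") return(fn(...))
  for (attempt in seq_len(retries + 1)) {
    job <- parallel::mcparallel(fn(...))
    res <- parallel::mccollect(job)[[1]]
    if (!is.null(res) && !inherits(res, "try-error")) return(res)
  }
  fn(...)
}
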