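# Prevalence filtering and counts-per-million normalization. The two
# analysis stages use the same operations at different strictness: the
# differential-expression stage keeps miRNAs with >= 2 counts in more than
# 50% of samples and hands raw counts to the NB test; the machine-learning
# stage filters at more than 80% and feeds CPM values.

#' Filter miRNAs by detection prevalence
#'
#' Keeps miRNA i iff the number of samples with at least `min_count` counts
#' strictly exceeds `min_fraction` of the samples. The sample set is
#' unchanged; the operation is idempotent.
#'
#' @inheritParams count_matrix
#' @param min_count Per-sample detection threshold, default 2 counts.
#' @param min_fraction Required fraction of samples (strict ">"), in [0, 1).
#' @return Filtered wide count tibble.
#' @export
prevalence_filter <- function(counts, min_count = 2, min_fraction) {
  check_count_tbl(counts)
  stopifnot(min_fraction >= 0, min_fraction < 1)
  m <- count_matrix(counts)
  keep <- rowSums(m >= min_count) > min_fraction * ncol(m)
  counts[keep, ]
}

#' Counts-per-million normalization
#'
#' values[i, j] = counts[i, j] / total_j x 10^6. By default `total_j` is the
#' column sum of the input, so every column of the result sums to 10^6.
#' Pass `totals` to normalize against totals computed upstream (e.g. over
#' all quantified miRNAs before prevalence filtering, the pipeline's
#' convention: totals are fixed at sample-QC time).
#'
#' @inheritParams count_matrix
#' @param totals Optional named per-sample totals; defaults to the input's
#'   column sums.
#' @return Wide tibble of CPM values.
#' @export
cpm_normalize <- function(counts, totals = NULL) {
  m <- count_matrix(counts)
  if (is.null(totals)) {
    totals <- colSums(m)
  } else {
    stopifnot(all(colnames(m) %in% names(totals)))
    totals <- totals[colnames(m)]
  }
  zero <- names(totals)[totals <= 0]
  if (length(zero) > 0) {
    abort(paste0("samples with zero total counts cannot be CPM-normalized: ",
                 paste(zero, collapse = ", ")))
  }
  as_count_tbl(sweep(m, 2, totals, "/") * 1e6)
}
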