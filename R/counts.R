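#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr %>%
NULL

# A count table is a wide tibble: first column `mirna` (character, unique),
# one numeric column per sample. Sample metadata is one row per sample with
# at least `sample_id`; classifier/evaluation functions additionally use
# `cohort`, `stage`, `age`, `sex`, `risk_factors`, `ca19_9`.

#' Convert a wide count tibble to a numeric matrix
#'
#' @param counts Wide count tibble (`mirna` column + one column per sample).
#' @return Numeric matrix, rownames = miRNA ids, colnames = sample ids.
#' @export
count_matrix <- function(counts) {
  check_count_tbl(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "mirna"), drop = FALSE])
  rownames(m) <- counts$mirna
  m
}

#' Wrap a numeric matrix as a wide count tibble
#'
#' @param m Numeric matrix with rownames (miRNA ids) and colnames (sample ids).
#' @return Wide count tibble.
#' @export
as_count_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(mirna = rownames(m)), as_tibble(m))
}

check_count_tbl <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || !"mirna" %in% names(counts)) {
    abort(sprintf("`%s` must be a data frame with a `mirna` column.", arg))
  }
  sample_cols <- setdiff(names(counts), "mirna")
  if (length(sample_cols) == 0L || nrow(counts) == 0L) {
    abort(sprintf("`%s` has no samples or no miRNAs.", arg))
  }
  if (!all(vapply(counts[sample_cols], is.numeric, logical(1)))) {
    abort(sprintf("all sample columns of `%s` must be numeric.", arg))
  }
  invisible(counts)
}

#' Per-sample total counts
#'
#' Column sums of the count table, the quantity the sequencing-depth QC
#' filter and CPM normalization operate on.
#'
#' @inheritParams count_matrix
#' @return Named numeric vector of per-sample totals.
#' @export
count_totals <- function(counts) {
  colSums(count_matrix(counts))
}

#' Number of miRNA species detected per sample
#'
#' A miRNA counts as detected in a sample when it has at least `min_count`
#' (default 2) deduplicated counts.
#'
#' @inheritParams count_matrix
#' @param min_count Detection threshold (counts), default 2.
#' @return Named integer vector, one entry per sample.
#' @export
species_detected <- function(counts, min_count = 2) {
  colSums(count_matrix(counts) >= min_count)
}

#' Read / write a tab-separated count table
#'
#' Rows are miRNAs (first column `mirna`), columns are samples.
#'
#' @param path File path.
#' @return `read_count_tbl()` returns the wide count tibble.
#' @export
read_count_tbl <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  check_count_tbl(counts)
  counts
}

#' @rdname read_count_tbl
#' @inheritParams count_matrix
#' @export
write_count_tbl <- function(counts, path) {
  check_count_tbl(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' One row per sample. The `risk_factors` column, when present, is a
#' semicolon-separated label set.
#'
#' @param path File path.
#' @export
read_sample_meta <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_sample_meta
#' @param meta Sample metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

# run code under a private RNG stream without touching the caller's state
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
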