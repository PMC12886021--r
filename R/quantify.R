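# UMI-deduplicated miRNA quantification from raw small-RNA reads.
# Read layout: [miRNA insert][3' adapter][12-bp UMI][optional filler].
# Pipeline per sample: adapter search -> insert length filter -> exact
# prefix assignment against the reference -> UMI deduplication.

#' Read layout of a small-RNA library
#'
#' @param adapter Non-empty 3' adapter sequence (kit-specific; required).
#' @param umi_length UMI length in bases following the adapter, default 12.
#' @param min_insert_length Minimum accepted insert length, default 20
#'   (inserts must exceed 19 bp).
#' @return A `uromir_layout` list.
#' @export
read_layout <- function(adapter, umi_length = 12, min_insert_length = 20) {
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    abort("`adapter` must be a non-empty sequence.")
  }
  stopifnot(umi_length >= 1, min_insert_length >= 1)
  structure(list(adapter = adapter, umi_length = as.integer(umi_length),
                 min_insert_length = as.integer(min_insert_length)),
            class = "uromir_layout")
}

#' Extract miRNA insert and UMI from raw reads
#'
#' The insert is everything before the first exact occurrence of the 3'
#' adapter; the UMI is the `umi_length` bases immediately after it.
#' Rejection is a value, not an error: reads fail with reason `no_adapter`,
#' `short_insert` (insert below `min_insert_length`) or `short_umi`.
#'
#' @param reads Character vector of read sequences (or tibble with a
#'   `sequence` column).
#' @param layout A [read_layout()].
#' @return Tibble with `sequence`, `insert`, `umi`, `accepted`, `reason`.
#' @export
extract_insert_umi <- function(reads, layout) {
  stopifnot(inherits(layout, "uromir_layout"))
  if (is.data.frame(reads)) reads <- reads$sequence
  pos <- regexpr(layout$adapter, reads, fixed = TRUE)
  has_adapter <- pos > 0
  insert <- ifelse(has_adapter, substr(reads, 1L, pos - 1L), NA_character_)
  umi_start <- pos + nchar(layout$adapter)
  umi <- ifelse(has_adapter,
                substr(reads, umi_start, umi_start + layout$umi_length - 1L),
                NA_character_)
  reason <- rep(NA_character_, length(reads))
  reason[!has_adapter] <- "no_adapter"
  short_ins <- has_adapter & nchar(insert) < layout$min_insert_length
  reason[short_ins] <- "short_insert"
  short_umi <- has_adapter & !short_ins & nchar(umi) < layout$umi_length
  reason[short_umi] <- "short_umi"
  tibble(sequence = reads, insert = insert, umi = umi,
         accepted = is.na(reason), reason = reason)
}

#' Assign inserts to reference miRNAs by exact prefix match
#'
#' An insert is assigned to the reference entry whose full sequence it
#' matches exactly over the reference length (references are at most 25 nt,
#' so a no-mismatch 25-bp seed policy reduces to full-length prefix match).
#' Reverse-complement matches are never considered. On a prefix-free
#' reference at most one entry can match; should several match, the insert
#' is counted as unassigned with a warning.
#'
#' @param inserts Character vector of accepted inserts.
#' @param ref Reference tibble (`mirna_id`, `sequence`).
#' @return Character vector of miRNA ids, `NA` where unassigned.
#' @export
assign_mirna <- function(inserts, ref) {
  hits <- matrix(NA_character_, nrow = length(inserts), ncol = 0)
  out <- rep(NA_character_, length(inserts))
  n_hit <- integer(length(inserts))
  for (L in sort(unique(nchar(ref$sequence)))) {
    grp <- ref[nchar(ref$sequence) == L, ]
    idx <- match(substr(inserts, 1L, L), grp$sequence)
    # a shorter insert can never fully cover a length-L reference
    idx[nchar(inserts) < L] <- NA_integer_
    found <- !is.na(idx)
    out[found] <- grp$mirna_id[idx[found]]
    n_hit <- n_hit + found
  }
  if (any(n_hit > 1)) {
    warn(sprintf("%d insert(s) matched multiple references; counted as unassigned.",
                 sum(n_hit > 1)))
    out[n_hit > 1] <- NA_character_
  }
  out
}

#' Collapse PCR duplicates by UMI
#'
#' Counts, per miRNA, the number of distinct UMIs observed — the estimated
#' number of original molecules. Order-invariant.
#'
#' @param assignments Tibble with `mirna_id` and `umi` (one row per assigned
#'   read).
#' @return Tibble with `mirna_id`, `count`.
#' @export
deduplicate_umis <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(mirna_id = character(), count = integer()))
  }
  assignments %>%
    dplyr::distinct(.data$mirna_id, .data$umi) %>%
    dplyr::count(.data$mirna_id, name = "count") %>%
    dplyr::arrange(.data$mirna_id)
}

#' Quantify one FASTQ sample into UMI-deduplicated miRNA counts
#'
#' Runs adapter/UMI extraction, the insert length filter, exact-prefix
#' reference assignment and UMI deduplication. Deterministic and invariant
#' to read order.
#'
#' @param fastq Path to a FASTQ file (optionally gzipped) or a character
#'   vector of read sequences.
#' @param ref Reference tibble (`mirna_id`, `sequence`).
#' @param layout A [read_layout()].
#' @return List with `counts` (tibble `mirna_id`, `count`, one row per
#'   reference entry) and `qc` (one-row tibble: `n_reads`, `n_adapter`,
#'   `n_assigned`, `total_counts`, `species_detected`).
#' @export
quantify_sample <- function(fastq, ref, layout) {
  reads <- if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else {
    as.character(fastq)
  }
  ext <- extract_insert_umi(reads, layout)
  acc <- ext[ext$accepted, ]
  ids <- assign_mirna(acc$insert, ref)
  assigned <- tibble(mirna_id = ids, umi = acc$umi)[!is.na(ids), ]
  dedup <- deduplicate_umis(assigned)
  counts <- tibble(mirna_id = ref$mirna_id,
                   count = dedup$count[match(ref$mirna_id, dedup$mirna_id)])
  counts$count[is.na(counts$count)] <- 0L
  qc <- tibble(
    n_reads = length(reads),
    n_adapter = length(reads) - sum(ext$reason %in% "no_adapter"),
    n_assigned = nrow(assigned),
    total_counts = sum(counts$count),
    species_detected = sum(counts$count >= 2)
  )
  list(counts = counts, qc = qc)
}

# Strict 4-line FASTQ reader (plain or gzipped): malformed records are a
# parse error naming the first offending record index.
read_fastq_sequences <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) return(character())
  idx <- locate_malformed_record(lines)
  if (!is.na(idx)) {
    abort(sprintf("malformed FASTQ record at index %d in '%s'", idx, path))
  }
  lines[seq(2, length(lines), by = 4)]
}

locate_malformed_record <- function(lines) {
  n_rec <- ceiling(length(lines) / 4)
  for (i in seq_len(n_rec)) {
    rec <- lines[(4 * (i - 1) + 1):min(4 * i, length(lines))]
    if (length(rec) < 4 || !startsWith(rec[1], "@") || !startsWith(rec[3], "+") ||
        nchar(rec[2]) != nchar(rec[4]) ||
        grepl("[^ACGTUN]", rec[2])) {
      return(i)
    }
  }
  NA_integer_
}

#' Quantify many FASTQ samples into a count table
#'
#' @param fastqs Named character vector of FASTQ paths (names become sample
#'   ids) or a named list of read vectors.
#' @inheritParams quantify_sample
#' @return List with `counts` (wide count tibble) and `qc` (tibble, one row
#'   per sample).
#' @export
quantify_samples <- function(fastqs, ref, layout) {
  stopifnot(!is.null(names(fastqs)), all(nzchar(names(fastqs))))
  per <- purrr::map(fastqs, quantify_sample, ref = ref, layout = layout)
  counts <- purrr::reduce(
    purrr::imap(per, function(x, nm) stats::setNames(x$counts, c("mirna", nm))),
    dplyr::left_join, by = "mirna")
  qc <- dplyr::bind_cols(tibble(sample_id = names(fastqs)),
                         dplyr::bind_rows(purrr::map(per, "qc")))
  list(counts = counts, qc = qc)
}

#' Drop samples with insufficient sequencing depth
#'
#' Keeps samples whose total miRNA count strictly exceeds `min_total`
#' (default 10^4).
#'
#' @inheritParams count_matrix
#' @param min_total Depth threshold; samples must exceed it to be kept.
#' @return List with `counts` (filtered tibble) and `dropped` (character
#'   vector of removed sample ids).
#' @export
qc_filter_samples <- function(counts, min_total = 1e4) {
  totals <- count_totals(counts)
  dropped <- names(totals)[totals <= min_total]
  list(counts = counts[, c("mirna", setdiff(names(counts), c("mirna", dropped)))],
       dropped = dropped)
}
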