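# Small fixtures built in code; designs are scaled down (fewer miRNAs,
# smaller library sizes) so tests stay fast while keeping the generative
# structure.

TEST_ADAPTER <- "AGATCGGAAGAGCACACGTC"

small_layout <- function() read_layout(TEST_ADAPTER)

# two-group design: PDAC all at one stage vs HR, constant stage multiplier,
# so the planted log2 fold change is exactly `lfc` for every cancer sample
two_group_design <- function(n_pdac = 60, n_hr = 60, n_mirnas = 100,
                             n_informative = 10, n_up = n_informative,
                             lfc = 2, dispersion = 0.2, seed = 1,
                             libsize_log_mean = log(5e4)) {
  cohort_design(
    n_pdac_by_stage = c(IV = n_pdac), n_hr = n_hr, n_general = 0, n_other = 0,
    n_mirnas = n_mirnas, n_informative = n_informative, n_up = n_up,
    lfc_stage_iv = lfc,
    stage_multiplier = c("0" = 1, IA = 1, IB = 1, IIA = 1, IIB = 1,
                         III = 1, IV = 1),
    dispersion = dispersion,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = 0.3,
    n_qc_fail = c(PDAC = 0, HR = 0), seed = seed)
}

# staged design with nonzero counts at every ordinal stage level
staged_design <- function(n_per_stage = 15, n_hr = 40, n_mirnas = 200,
                          n_informative = 0, lfc = 0, seed = 1) {
  cohort_design(
    n_pdac_by_stage = c(IA = n_per_stage, IIA = n_per_stage,
                        III = n_per_stage, IV = n_per_stage),
    n_hr = n_hr, n_general = 0, n_other = 0,
    n_mirnas = n_mirnas, n_informative = n_informative,
    n_up = min(n_informative, max(0, n_informative - 2)),
    lfc_stage_iv = lfc, dispersion = 0.2,
    libsize_log_mean = log(5e4), libsize_log_sd = 0.3,
    n_qc_fail = c(PDAC = 0, HR = 0), seed = seed)
}

pdac_hr_subset <- function(cohort) {
  keep <- cohort$meta$cohort %in% c("PDAC", "HR")
  list(counts = cohort$counts[, c("mirna", cohort$meta$sample_id[keep])],
       meta = cohort$meta[keep, ])
}

# feature matrix + labels for classifier tests
small_feature_problem <- function(n = 80, p = 20, n_inf = 3, effect = 2,
                                  seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    y <- rep(0:1, length.out = n)
    x[, seq_len(n_inf)] <- x[, seq_len(n_inf)] + effect * y
    list(x = x, y = y)
  })
}
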