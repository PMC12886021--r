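# Synthetic cohorts emulating a urinary-EV small-RNA study: negative-binomial
# miRNA counts with lognormal library sizes, a planted panel of differential
# miRNAs with stage-dependent fold changes, and demographics/CA19-9 covariates.

STAGES <- c("0", "IA", "IB", "IIA", "IIB", "III", "IV")
RISK_FACTORS <- c("ductal_dilation", "T2DM", "chronic_pancreatitis",
                  "pancreatic_cysts", "IPMN", "family_history")

#' Generate a prefix-free mature miRNA reference
#'
#' Draws `n_mirnas` random sequences of 18-25 nt (the mature miRNA length
#' range) over A/C/G/U-free DNA alphabet A/C/G/T. The set is prefix-free: no
#' sequence is a strict prefix of another, so exact-prefix read assignment is
#' unambiguous.
#'
#' @param n_mirnas Number of reference entries (>= 1).
#' @param seed Integer seed; the result is a pure function of it.
#' @param len_range Inclusive sequence-length range within 18-25 nt. Use
#'   `c(20, 25)` when every reference entry must survive the default
#'   `>19 bp` insert length filter of the quantifier.
#' @return Tibble with columns `mirna_id`, `sequence`.
#' @export
generate_reference <- function(n_mirnas, seed = 1, len_range = c(18, 25)) {
  if (!is.numeric(n_mirnas) || length(n_mirnas) != 1 || n_mirnas < 1) {
    abort("`n_mirnas` must be a single integer >= 1.")
  }
  stopifnot(len_range[1] >= 18, len_range[2] <= 25, len_range[1] <= len_range[2])
  n_mirnas <- as.integer(n_mirnas)
  lens <- len_range[1]:len_range[2]
  with_rng(seed, {
    seqs <- random_seqs(n_mirnas, sample(lens, n_mirnas, replace = TRUE))
    # redraw any sequence involved in a prefix relation until the set is clean
    repeat {
      bad <- prefix_conflicts(seqs)
      if (length(bad) == 0L) break
      seqs[bad] <- random_seqs(length(bad), sample(lens, length(bad), replace = TRUE))
    }
    tibble(
      mirna_id = sprintf("mir-%04d", seq_len(n_mirnas)),
      sequence = seqs
    )
  })
}

random_seqs <- function(n, lens) {
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# indices of sequences that are a strict prefix of another or duplicated;
# after lexicographic sort, any prefix pair is adjacent
prefix_conflicts <- function(seqs) {
  o <- order(seqs, method = "radix")
  s <- seqs[o]
  bad <- logical(length(s))
  for (i in seq_len(length(s) - 1)) {
    if (startsWith(s[i + 1], s[i])) bad[i] <- bad[i + 1] <- TRUE
  }
  sort(o[bad])
}

#' Simulate a small-RNA FASTQ sample with UMIs and PCR duplicates
#'
#' Each molecule is a miRNA drawn from `abundance`, tagged with one random
#' UMI, and emitted as `1 + Poisson(pcr_lambda)` identical reads of layout
#' `insert + adapter + UMI` (the 12-bp UMI follows the 3' adapter). UMIs
#' are drawn distinct across molecules (no tag collisions), so on
#' error-free reads UMI deduplication recovers the molecule count per
#' miRNA — the returned ground truth — exactly.
#'
#' @param ref Reference tibble from [generate_reference()].
#' @param abundance Probability vector over reference entries (sums to 1).
#' @param n_molecules Number of cDNA molecules to emit.
#' @param adapter Non-empty 3' adapter sequence.
#' @param umi_len UMI length in bases, default 12.
#' @param pcr_lambda Poisson rate of extra PCR copies per molecule.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id`, `sequence`), `truth`
#'   (tibble `mirna_id`, `molecules`).
#' @export
simulate_fastq_sample <- function(ref, abundance = NULL, n_molecules,
                                  adapter, umi_len = 12, pcr_lambda = 1,
                                  seed = 1) {
  if (is.null(ref) || nrow(ref) == 0) abort("`ref` must be a non-empty reference.")
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    abort("`adapter` must be a non-empty sequence.")
  }
  if (is.null(abundance)) abundance <- rep(1 / nrow(ref), nrow(ref))
  if (length(abundance) != nrow(ref)) abort("`abundance` length must match `ref`.")
  if (abs(sum(abundance) - 1) > 1e-8) abort("`abundance` must sum to 1.")
  with_rng(seed, {
    idx <- sample.int(nrow(ref), n_molecules, replace = TRUE, prob = abundance)
    umis <- random_seqs(n_molecules, rep(umi_len, n_molecules))
    while (anyDuplicated(umis) > 0) {
      dup <- duplicated(umis)
      umis[dup] <- random_seqs(sum(dup), rep(umi_len, sum(dup)))
    }
    copies <- 1L + stats::rpois(n_molecules, pcr_lambda)
    rep_idx <- rep(seq_len(n_molecules), copies)
    reads <- tibble(
      read_id = sprintf("read_%06d", seq_along(rep_idx)),
      sequence = paste0(ref$sequence[idx[rep_idx]], adapter, umis[rep_idx])
    )
    truth <- tibble(
      mirna_id = ref$mirna_id,
      molecules = tabulate(idx, nbins = nrow(ref))
    )
    list(reads = reads, truth = truth)
  })
}

#' Write reads as FASTQ / a reference as FASTA
#'
#' FASTQ records are 4-line with constant Phred+33 quality "I"; a `.gz`
#' suffix triggers gzip compression.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @param ref Reference tibble (`mirna_id`, `sequence`).
#' @export
write_fasta <- function(ref, path) {
  writeLines(paste0(">", ref$mirna_id, "\n", ref$sequence), path)
  invisible(path)
}

#' Cohort design for the count simulator
#'
#' Defaults emulate the study conditions of a multi-arm pancreatic-cancer
#' cohort: 140 PDAC samples spread over TNM stages 0-IV, 110 high-risk (HR)
#' samples carrying at least one of six pancreatic risk factors, 5
#' other-histology cancers and 26 general-population samples; lognormal
#' library sizes with medians near 1.2-1.7 million total counts; a planted
#' panel of 16 differential miRNAs (11 up, 5 down in cancer) whose log2 fold
#' changes grow monotonically with stage; age/sex distributions and CA19-9
#' levels per arm. One PDAC and one HR sample are planted as sequencing-depth
#' QC failures.
#'
#' @param n_pdac_by_stage Named counts per TNM stage for the PDAC arm.
#' @param n_hr,n_general,n_other Sizes of the HR, general-population and
#'   other-histology arms.
#' @param n_mirnas Number of miRNA species simulated.
#' @param n_informative,n_up Planted differential miRNAs (total, upregulated).
#' @param lfc_stage_iv Log2 fold change of the planted panel at stage IV
#'   (downregulated members get the negative); scaled per stage by
#'   `stage_multiplier`.
#' @param stage_multiplier Named per-stage scaling of the planted log2 fold
#'   changes (monotone in stage by default).
#' @param dispersion NB dispersion alpha in Var = mu + alpha * mu^2.
#' @param libsize_log_mean,libsize_log_sd Lognormal library-size parameters
#'   (natural-log scale) for the PDAC/HR/other arms.
#' @param general_libsize_factor Multiplier on the general arm's median
#'   library size (general-population urine yields fewer counts).
#' @param qc_fail_libsize Library size assigned to planted QC-failure samples.
#' @param n_qc_fail Named counts of planted QC failures per arm.
#' @param pcr_lambda Poisson PCR-duplication rate (read-level simulation).
#' @param seed Integer seed.
#' @return A `uromir_design` list validated for [simulate_cohort_counts()].
#' @export
cohort_design <- function(
    n_pdac_by_stage = c("0" = 2, IA = 16, IB = 15, IIA = 9,
                        IIB = 25, III = 31, IV = 42),
    n_hr = 110, n_general = 26, n_other = 5,
    n_mirnas = 400, n_informative = 16, n_up = 11,
    lfc_stage_iv = 0.45,
    stage_multiplier = c("0" = 0.25, IA = 0.5, IB = 0.5, IIA = 0.75,
                         IIB = 0.75, III = 1, IV = 1.25),
    dispersion = 0.2,
    libsize_log_mean = log(1.6e6), libsize_log_sd = 0.5,
    general_libsize_factor = 0.75,
    qc_fail_libsize = 3e3,
    n_qc_fail = c(PDAC = 1, HR = 1),
    pcr_lambda = 1,
    seed = 1) {
  stopifnot(all(n_pdac_by_stage >= 0), n_hr >= 0, n_general >= 0, n_other >= 0,
            dispersion > 0, n_informative <= n_mirnas, n_up <= n_informative,
            all(names(n_pdac_by_stage) %in% STAGES))
  design <- list(
    n_pdac_by_stage = n_pdac_by_stage, n_hr = n_hr, n_general = n_general,
    n_other = n_other, n_mirnas = as.integer(n_mirnas),
    n_informative = as.integer(n_informative), n_up = as.integer(n_up),
    lfc_stage_iv = lfc_stage_iv, stage_multiplier = stage_multiplier,
    dispersion = dispersion,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    general_libsize_factor = general_libsize_factor,
    qc_fail_libsize = qc_fail_libsize, n_qc_fail = n_qc_fail,
    pcr_lambda = pcr_lambda, seed = as.integer(seed),
    # demographics (mean age, sd, male fraction) per arm
    age = list(PDAC = c(69.8, 10.1), other_histology = c(70.8, 9.8),
               HR = c(70.5, 8.4), general = c(38.7, 18.9)),
    p_male = c(PDAC = 0.57, other_histology = 0.60, HR = 0.55, general = 0.48),
    risk_factor_prob = c(ductal_dilation = 15, T2DM = 48,
                         chronic_pancreatitis = 26, pancreatic_cysts = 19,
                         IPMN = 51, family_history = 43) / 109,
    # CA19-9 lognormal parameters calibrated so the 37 U/mL rule reproduces
    # sensitivities near 0.34 (early), 0.81 (late) and specificity near 0.75
    ca19_9 = list(hr = c(log(13), 1.55), early = c(log(20), 1.5),
                  late = c(log(120), 1.3),
                  p_missing = c(PDAC = 5 / 139, HR = 34 / 109))
  )
  class(design) <- "uromir_design"
  design
}

# per-miRNA log2 fold change at a given stage under a design's planted panel
design_lfc_matrix <- function(design) {
  base <- c(rep(design$lfc_stage_iv / design$stage_multiplier[["IV"]],
                design$n_up),
            rep(-design$lfc_stage_iv / design$stage_multiplier[["IV"]],
                design$n_informative - design$n_up))
  lfc <- matrix(0, nrow = length(STAGES), ncol = design$n_mirnas,
                dimnames = list(STAGES, NULL))
  if (design$n_informative > 0) {
    for (s in STAGES) {
      lfc[s, seq_len(design$n_informative)] <- base * design$stage_multiplier[[s]]
    }
  }
  lfc
}

#' Simulate a cohort-level miRNA count matrix with metadata
#'
#' Counts are NB(mean = libsize_j x baseline_i x 2^lfc(stage_j), dispersion)
#' with lognormal library sizes. HR, general-population and stage-free
#' samples receive zero planted effects; other-histology samples share the
#' PDAC stage effects. Deterministic under the design seed.
#'
#' @param design A [cohort_design()].
#' @return A `uromir_cohort` list: `counts` (wide tibble), `meta` (tibble with
#'   `sample_id`, `cohort`, `stage`, `age`, `sex`, `risk_factors`, `ca19_9`),
#'   and `truth` (generative parameters: baselines, library sizes, planted
#'   panel, design).
#' @export
simulate_cohort_counts <- function(design) {
  stopifnot(inherits(design, "uromir_design"))
  with_rng(design$seed, {
    n_pdac <- sum(design$n_pdac_by_stage)
    arms <- c(rep("PDAC", n_pdac),
              rep("other_histology", design$n_other),
              rep("HR", design$n_hr),
              rep("general", design$n_general))
    n <- length(arms)
    stage <- rep("none", n)
    stage[arms == "PDAC"] <- rep(names(design$n_pdac_by_stage),
                                 design$n_pdac_by_stage)
    if (design$n_other > 0) {
      stage[arms == "other_histology"] <-
        sample(STAGES, design$n_other, replace = TRUE)
    }
    meta <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      cohort = arms,
      stage = stage,
      age = round(pmin(95, pmax(18, stats::rnorm(
        n,
        vapply(arms, function(a) design$age[[a]][1], numeric(1)),
        vapply(arms, function(a) design$age[[a]][2], numeric(1)))))),
      sex = ifelse(stats::runif(n) < design$p_male[arms], "M", "F")
    )
    meta$risk_factors <- vapply(arms, function(a) {
      if (a != "HR") return(NA_character_)
      hit <- stats::runif(length(RISK_FACTORS)) < design$risk_factor_prob
      if (!any(hit)) {
        hit[sample.int(length(RISK_FACTORS), 1,
                       prob = design$risk_factor_prob)] <- TRUE
      }
      paste(RISK_FACTORS[hit], collapse = ";")
    }, character(1))
    meta$ca19_9 <- simulate_ca199(meta, design)

    # baseline relative abundances and library sizes
    w <- stats::rlnorm(design$n_mirnas, 0, 1.5)
    baseline <- w / sum(w)
    ls_mean <- design$libsize_log_mean +
      ifelse(arms == "general", log(design$general_libsize_factor), 0)
    libsize <- stats::rlnorm(n, ls_mean, design$libsize_log_sd)
    for (arm in names(design$n_qc_fail)) {
      k <- design$n_qc_fail[[arm]]
      if (k > 0) {
        pick <- utils::tail(which(arms == arm), k)
        libsize[pick] <- design$qc_fail_libsize
      }
    }

    lfc <- design_lfc_matrix(design)
    mu <- sample_means(baseline, libsize, lfc, meta$cohort, meta$stage)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
      nrow = design$n_mirnas,
      dimnames = list(sprintf("mir-%04d", seq_len(design$n_mirnas)),
                      meta$sample_id))
    structure(
      list(counts = as_count_tbl(counts), meta = meta,
           truth = list(baseline = baseline, libsize = stats::setNames(libsize, meta$sample_id),
                        lfc = lfc,
                        informative = rownames(counts)[seq_len(design$n_informative)],
                        design = design)),
      class = "uromir_cohort")
  })
}

simulate_ca199 <- function(meta, design) {
  p <- design$ca19_9
  early <- c("0", "IA", "IB", "IIA")
  vapply(seq_len(nrow(meta)), function(j) {
    arm <- meta$cohort[j]
    if (arm == "general") return(NA_real_)
    par <- if (arm == "HR") p$hr
           else if (meta$stage[j] %in% early) p$early else p$late
    miss_p <- if (arm == "HR") p$p_missing[["HR"]] else p$p_missing[["PDAC"]]
    if (stats::runif(1) < miss_p) return(NA_real_)
    round(stats::rlnorm(1, par[1], par[2]), 1)
  }, numeric(1))
}

# expected NB means: miRNA x sample, cancer arms get stage-dependent lfc
sample_means <- function(baseline, libsize, lfc, cohort, stage) {
  m <- length(baseline); n <- length(libsize)
  mu <- outer(baseline, libsize)
  cancer <- cohort %in% c("PDAC", "other_histology") & stage %in% rownames(lfc)
  for (j in which(cancer)) {
    mu[, j] <- mu[, j] * 2^lfc[stage[j], ]
  }
  mu
}

#' Analytic log-likelihood-ratio oracle scores
#'
#' Scores each sample with log L(counts | PDAC stage mixture) - log
#' L(counts | HR) using the cohort's true generative parameters (baseline
#' abundances, per-sample library sizes, planted fold changes, dispersion).
#' The mixture weights are the design's PDAC stage proportions. The AUC of
#' these Bayes-optimal scores asymptotically upper-bounds any classifier
#' trained on the same count features.
#'
#' @param cohort A `uromir_cohort` from [simulate_cohort_counts()].
#' @param counts Count tibble to score; defaults to the cohort's own. Its
#'   samples must be present in the cohort truth (library sizes are looked up
#'   by sample id).
#' @return Tibble with `sample_id`, `oracle_score`.
#' @export
oracle_scores <- function(cohort, counts = cohort$counts) {
  stopifnot(inherits(cohort, "uromir_cohort"))
  truth <- cohort$truth
  y <- count_matrix(counts)
  if (nrow(y) != length(truth$baseline)) {
    abort("`counts` has a different number of miRNAs than the design.")
  }
  if (!all(colnames(y) %in% names(truth$libsize))) {
    abort("`counts` contains samples unknown to the cohort truth.")
  }
  libsize <- truth$libsize[colnames(y)]
  alpha <- truth$design$dispersion
  stage_w <- truth$design$n_pdac_by_stage / sum(truth$design$n_pdac_by_stage)
  mu0 <- outer(truth$baseline, libsize)
  ll_hr <- colSums(stats::dnbinom(y, size = 1 / alpha, mu = mu0, log = TRUE))
  ll_stage <- vapply(names(stage_w), function(s) {
    mus <- mu0 * 2^truth$lfc[s, ]
    colSums(stats::dnbinom(y, size = 1 / alpha, mu = mus, log = TRUE))
  }, numeric(ncol(y)))
  if (ncol(y) == 1L) ll_stage <- matrix(ll_stage, nrow = 1)
  lw <- sweep(ll_stage, 2, log(stage_w), "+")
  mx <- apply(lw, 1, max)
  ll_pdac <- mx + log(rowSums(exp(lw - mx)))
  tibble(sample_id = colnames(y), oracle_score = ll_pdac - ll_hr)
}
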