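# Seeded generator of two-sample GWAS summary statistics with known ground
# truth: causal effect, pleiotropy architecture, instrument strength, LD
# blocks, palindromic variants and strand/allele-label corruptions. Every
# pipeline stage is testable against the recorded truth without external
# data.
#
# Generative model (standard two-sample MR): per instrument locus j,
#   gamma_j ~ Normal(0, gamma_sd^2)           true effect on the exposure
#   alpha_j ~ Normal(mu_alpha, sd_alpha^2)    direct (pleiotropic) effect,
#                                             attached to the
#                                             exposure-increasing allele
#   beta_exp_j ~ Normal(gamma_j, se_xj^2),  se_xj = 1/sqrt(2 maf(1-maf) n_x)
#   beta_out_j ~ Normal(theta gamma_j + sign(gamma_j) alpha_j, se_yj^2)
# Binary outcomes are generated directly on the log-odds scale with
# se_yj = 1/sqrt(2 maf(1-maf) n_y cf (1-cf)), cf the case fraction.

NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                     c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Configuration for the synthetic summary-statistics generator
#'
#' Defaults describe a well-powered two-sample design: a causal effect of
#' 0.1 SD per SD, 30 independent instrument loci with per-SD effects of
#' spread 0.1 (per-variant F broadly between ~20 and a few thousand at
#' these sample sizes), exposure GWAS of 50,000 and outcome GWAS of
#' 100,000, no pleiotropy, and no file corruptions.
#'
#' @param theta True causal effect (SD outcome per SD exposure; log-odds
#'   per SD when `binary_outcome`).
#' @param n_instruments Number of instrument loci (LD blocks).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param gamma_sd SD of true instrument effects on the exposure (per-SD
#'   scale).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct effects on
#'   the outcome; mean 0 with positive SD is balanced pleiotropy, nonzero
#'   mean is directional.
#' @param inside_violation If `TRUE`, direct effects gain a component
#'   proportional to instrument strength (`inside_lambda`), violating the
#'   InSIDE condition.
#' @param inside_lambda Strength of the InSIDE violation.
#' @param maf_range Interval within (0, 0.5\] for minor-allele frequencies.
#' @param n_null_variants Background variants with no exposure effect.
#' @param prop_palindromic Probability a variant gets A/T or G/C alleles.
#' @param prop_strand_flipped,prop_allele_swapped Probabilities that the
#'   outcome file reports a variant on the complementary strand / with
#'   effect and other allele labels exchanged (beta negated, frequency
#'   reflected). Both are representation changes the harmonizer must undo.
#' @param ld_block_size Variants per instrument locus; members beyond the
#'   lead tag it with squared correlation `ld_within_r2`.
#' @param ld_within_r2 Within-block squared correlation.
#' @param binary_outcome Generate the outcome on the log-odds scale.
#' @param case_fraction Case fraction of a binary outcome.
#' @param min_expected_f Resample instrument effects until the expected
#'   per-variant F-statistic exceeds this value (`NULL` to disable).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(theta = 0.1, n_instruments = 30, n_exposure = 50000,
                       n_outcome = 100000, gamma_sd = 0.1,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       inside_violation = FALSE, inside_lambda = 0.5,
                       maf_range = c(0.05, 0.5), n_null_variants = 0,
                       prop_palindromic = 0, prop_strand_flipped = 0,
                       prop_allele_swapped = 0, ld_block_size = 1,
                       ld_within_r2 = 0.8, binary_outcome = FALSE,
                       case_fraction = 0.41, min_expected_f = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_instruments < 1) stopf("need at least one instrument")
  if (cfg$n_exposure <= 2 || cfg$n_outcome <= 2) stopf("sample sizes must exceed 2")
  if (cfg$pleiotropy_sd < 0) stopf("pleiotropy_sd must be nonnegative")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an interval within (0, 0.5]")
  }
  for (p in c("prop_palindromic", "prop_strand_flipped", "prop_allele_swapped")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must lie in [0,1]", p)
  }
  if (cfg$ld_block_size < 1) stopf("ld_block_size must be >= 1")
  if (cfg$ld_within_r2 < 0 || cfg$ld_within_r2 > 1) stopf("ld_within_r2 in [0,1]")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1) stopf("case_fraction in (0,1)")
  structure(cfg, class = "sim_config")
}

se_from_maf <- function(maf, n, case_fraction = NULL) {
  v <- 2 * maf * (1 - maf) * n
  if (!is.null(case_fraction)) v <- v * case_fraction * (1 - case_fraction)
  1 / sqrt(v)
}

# Draw variant scaffolding (positions, alleles, frequencies) and true
# exposure effects for one study's instrument loci + null background.
# Assumes the RNG is already seeded by the caller.
sim_variant_truth <- function(cfg, id_prefix = "rs") {
  B <- cfg$ld_block_size
  n_inst_var <- cfg$n_instruments * B
  n_var <- n_inst_var + cfg$n_null_variants
  block <- c(rep(seq_len(cfg$n_instruments), each = B),
             cfg$n_instruments + seq_len(cfg$n_null_variants))
  within <- c(rep(seq_len(B), times = cfg$n_instruments),
              rep(1L, cfg$n_null_variants))
  maf <- stats::runif(n_var, cfg$maf_range[1], cfg$maf_range[2])

  # lead effects, resampled for expected instrument strength if configured
  gamma_lead <- stats::rnorm(cfg$n_instruments, 0, cfg$gamma_sd)
  if (!is.null(cfg$min_expected_f)) {
    lead_maf <- maf[match(seq_len(cfg$n_instruments), block)]
    se_x <- se_from_maf(lead_maf, cfg$n_exposure)
    for (j in seq_len(cfg$n_instruments)) {
      tries <- 0
      while ((gamma_lead[j] / se_x[j])^2 < cfg$min_expected_f) {
        gamma_lead[j] <- stats::rnorm(1, 0, cfg$gamma_sd)
        tries <- tries + 1
        if (tries > 10000) stopf("cannot reach min_expected_f; raise gamma_sd")
      }
    }
  }
  alpha_lead <- stats::rnorm(cfg$n_instruments, cfg$pleiotropy_mean,
                             cfg$pleiotropy_sd)
  if (cfg$inside_violation) {
    # correlate direct effects with instrument strength, mean preserved
    alpha_lead <- alpha_lead + cfg$inside_lambda *
      (abs(gamma_lead) - mean(abs(gamma_lead)))
  }
  is_inst <- block <= cfg$n_instruments
  gamma <- numeric(n_var)
  alpha <- numeric(n_var)
  gamma[is_inst] <- gamma_lead[block[is_inst]] *
    ifelse(within[is_inst] == 1, 1, sqrt(cfg$ld_within_r2))
  alpha[is_inst] <- alpha_lead[block[is_inst]]

  pal <- stats::runif(n_var) < cfg$prop_palindromic
  pair_idx_np <- sample.int(length(NONPAL_PAIRS), n_var, replace = TRUE)
  pair_idx_p <- sample.int(length(PAL_PAIRS), n_var, replace = TRUE)
  ea <- character(n_var); oa <- character(n_var)
  for (i in seq_len(n_var)) {
    pr <- if (pal[i]) PAL_PAIRS[[pair_idx_p[i]]] else NONPAL_PAIRS[[pair_idx_np[i]]]
    ea[i] <- pr[1]; oa[i] <- pr[2]
  }
  minor_is_effect <- stats::runif(n_var) < 0.5
  eaf <- ifelse(minor_is_effect, maf, 1 - maf)

  data.frame(
    variant_id = sprintf("%s%05d", id_prefix, seq_len(n_var)),
    chrom = as.character((block - 1L) %% 22L + 1L),
    pos = as.integer(1e6 + ((block - 1L) %/% 22L) * 5e7 + (within - 1L) * 1e4),
    effect_allele = ea, other_allele = oa, eaf = eaf, maf = maf,
    block = block, is_instrument = is_inst,
    gamma_true = gamma, alpha_true = alpha, palindromic = pal,
    stringsAsFactors = FALSE
  )
}

sim_sumstats_from_truth <- function(truth, beta_true, n, case_fraction,
                                    study) {
  se <- se_from_maf(truth$maf, n, case_fraction)
  beta <- stats::rnorm(nrow(truth), beta_true, se)
  df <- data.frame(
    variant_id = truth$variant_id, chrom = truth$chrom, pos = truth$pos,
    effect_allele = truth$effect_allele, other_allele = truth$other_allele,
    eaf = truth$eaf, beta = beta, se = se,
    pval = two_sided_normal_p(beta / se), n = n,
    stringsAsFactors = FALSE
  )
  df$pval_floored <- FALSE
  new_sumstats(df, study = study)
}

# Exchange effect/other allele labels and/or complement the strand of
# outcome records; both are pure representation changes the harmonizer
# must undo.
apply_corruptions <- function(records, prop_swap, prop_flip) {
  n <- nrow(records)
  swap <- stats::runif(n) < prop_swap
  flip <- stats::runif(n) < prop_flip
  ea <- records$effect_allele; oa <- records$other_allele
  records$effect_allele <- ifelse(swap, oa, ea)
  records$other_allele <- ifelse(swap, ea, oa)
  records$beta <- ifelse(swap, -records$beta, records$beta)
  records$eaf <- ifelse(swap, 1 - records$eaf, records$eaf)
  records$effect_allele <- ifelse(flip,
                                  complement_allele(records$effect_allele),
                                  records$effect_allele)
  records$other_allele <- ifelse(flip,
                                 complement_allele(records$other_allele),
                                 records$other_allele)
  attr(records, "swapped") <- swap
  attr(records, "flipped") <- flip
  records
}

block_ld_matrix <- function(truth, r2_within) {
  n <- nrow(truth)
  m <- diag(1, n)
  dimnames(m) <- list(truth$variant_id, truth$variant_id)
  for (b in unique(truth$block[truth$is_instrument])) {
    idx <- which(truth$block == b)
    if (length(idx) > 1) {
      m[idx, idx] <- r2_within
      diag(m)[idx] <- 1
    }
  }
  diag(m) <- 1
  ld_matrix(m)
}

#' Generate a matched exposure/outcome summary-statistics pair
#'
#' Draws instrument loci and background variants, simulates both studies'
#' summary statistics under the configured causal effect and pleiotropy
#' architecture, applies the configured allele-label and strand
#' corruptions to the outcome table, and returns everything with the
#' generating truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_study_pair"`: `exposure` and `outcome`
#'   (`"sumstats"` objects), `ld` (an [ld_matrix()] over all variants),
#'   `truth` (per-variant generating values and corruption flags) and
#'   `config`.
#' @export
generate_study_pair <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  with_private_seed(config$seed, {
    truth <- sim_variant_truth(config)
    exp_meta <- study_meta("exposure", trait_type = "continuous")
    out_meta <- if (config$binary_outcome) {
      ncase <- round(config$n_outcome * config$case_fraction)
      study_meta("outcome", trait_type = "binary", n_cases = ncase,
                 n_controls = config$n_outcome - ncase)
    } else {
      study_meta("outcome", trait_type = "continuous")
    }
    exposure <- sim_sumstats_from_truth(truth, truth$gamma_true,
                                        config$n_exposure, NULL, exp_meta)
    beta_out_true <- config$theta * truth$gamma_true +
      sign(truth$gamma_true) * truth$alpha_true
    cf <- if (config$binary_outcome) config$case_fraction else NULL
    outcome <- sim_sumstats_from_truth(truth, beta_out_true,
                                       config$n_outcome, cf, out_meta)
    outcome <- apply_corruptions(outcome, config$prop_allele_swapped,
                                 config$prop_strand_flipped)
    truth$allele_swapped <- attr(outcome, "swapped")
    truth$strand_flipped <- attr(outcome, "flipped")
    ld <- block_ld_matrix(truth, config$ld_within_r2)
    structure(list(exposure = exposure, outcome = outcome, ld = ld,
                   truth = truth, config = config),
              class = "sim_study_pair")
  })
}

#' @export
print.sim_study_pair <- function(x, ...) {
  cat(sprintf(
    "Synthetic two-sample study pair: theta = %g, %d instrument loci, %d variants\n",
    x$config$theta, x$config$n_instruments, nrow(x$truth)))
  invisible(x)
}

#' Generate a grid of synthetic studies with a manifest
#'
#' Emulates a many-exposure-by-few-outcome bidirectional design at any
#' scale: each exposure contributes its own instrument loci (plus null
#' background), each outcome its own disease instruments, and every study
#' file contains the records downstream analyses will look up (exposure
#' variants in all outcome files under the forward effects
#' `theta_forward`; outcome instruments in all exposure files under the
#' reverse effects `theta_reverse`). Files, LD matrices, per-study truth
#' tables and a manifest TSV are written to `dir`.
#'
#' @param exposure_configs List of [sim_config()], one per exposure.
#' @param exposure_labels Unique exposure study ids.
#' @param outcome_configs List of [sim_config()], one per outcome (its
#'   `n_outcome`, `binary_outcome`, `case_fraction` describe the disease
#'   GWAS; its `n_instruments`/`gamma_sd` the disease's own instruments).
#' @param outcome_labels Unique outcome study ids.
#' @param dir Output directory (created if needed).
#' @param theta_forward Matrix (exposures x outcomes) of true forward
#'   effects; defaults to each exposure config's `theta` for every
#'   outcome.
#' @param theta_reverse Matrix (outcomes x exposures) of true reverse
#'   effects; defaults to all zero.
#' @param seed Master seed for the grid.
#' @return The manifest data.frame (columns `study_id`, `role`, `path`,
#'   `trait_type`, `n`, `n_cases`, `n_controls`, `ld_path`, `truth_path`),
#'   invisibly; also written to `file.path(dir, "manifest.tsv")`.
#' @export
generate_grid <- function(exposure_configs, exposure_labels,
                          outcome_configs, outcome_labels, dir,
                          theta_forward = NULL, theta_reverse = NULL,
                          seed = 1) {
  E <- length(exposure_configs); O <- length(outcome_configs)
  if (length(exposure_labels) != E || length(outcome_labels) != O) {
    stopf("labels must match config lists in length")
  }
  labels <- c(exposure_labels, outcome_labels)
  if (anyDuplicated(labels)) stopf("duplicate study labels")
  if (is.null(theta_forward)) {
    theta_forward <- matrix(vapply(exposure_configs, `[[`, 0, "theta"), E, O)
  }
  if (is.null(theta_reverse)) theta_reverse <- matrix(0, O, E)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  with_private_seed(seed, {
    exp_truth <- vector("list", E)
    for (e in seq_len(E)) {
      exp_truth[[e]] <- sim_variant_truth(exposure_configs[[e]],
                                          id_prefix = sprintf("rsX%d_", e))
    }
    out_truth <- vector("list", O)
    for (o in seq_len(O)) {
      out_truth[[o]] <- sim_variant_truth(outcome_configs[[o]],
                                          id_prefix = sprintf("rsY%d_", o))
    }

    manifest <- list()
    emit <- function(study_id, role, records, meta, ld, truth_df) {
      path <- file.path(dir, paste0(study_id, ".tsv"))
      write_sumstats(records, path)
      ld_path <- NA_character_
      if (!is.null(ld)) {
        ld_path <- file.path(dir, paste0(study_id, ".ld.tsv"))
        write_ld_matrix(ld, ld_path)
      }
      truth_path <- file.path(dir, paste0(study_id, ".truth.tsv"))
      utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest[[length(manifest) + 1]] <<- data.frame(
        study_id = study_id, role = role, path = path,
        trait_type = meta$trait_type, n = NA_real_,
        n_cases = meta$n_cases %||% NA_real_,
        n_controls = meta$n_controls %||% NA_real_,
        ld_path = ld_path, truth_path = truth_path,
        stringsAsFactors = FALSE
      )
    }

    for (e in seq_len(E)) {
      cfg <- exposure_configs[[e]]
      tr <- exp_truth[[e]]
      meta <- study_meta(exposure_labels[e], trait_type = "continuous")
      own <- sim_sumstats_from_truth(tr, tr$gamma_true, cfg$n_exposure,
                                     NULL, meta)
      # reverse-instrument records: disease variants as seen in this
      # exposure's GWAS
      rev_rows <- lapply(seq_len(O), function(o) {
        trc <- out_truth[[o]]
        bt <- theta_reverse[o, e] * trc$gamma_true +
          sign(trc$gamma_true) * trc$alpha_true
        sim_sumstats_from_truth(trc, bt, cfg$n_exposure, NULL, meta)
      })
      all_recs <- do.call(rbind, c(list(as.data.frame(own)),
                                   lapply(rev_rows, as.data.frame)))
      recs <- new_sumstats(all_recs, study = meta)
      emit(exposure_labels[e], "exposure", recs, meta,
           block_ld_matrix(tr, cfg$ld_within_r2), tr)
    }

    for (o in seq_len(O)) {
      cfg <- outcome_configs[[o]]
      tro <- out_truth[[o]]
      meta <- if (cfg$binary_outcome) {
        ncase <- round(cfg$n_outcome * cfg$case_fraction)
        study_meta(outcome_labels[o], trait_type = "binary",
                   n_cases = ncase, n_controls = cfg$n_outcome - ncase)
      } else {
        study_meta(outcome_labels[o], trait_type = "continuous")
      }
      cf <- if (cfg$binary_outcome) cfg$case_fraction else NULL
      own <- sim_sumstats_from_truth(tro, tro$gamma_true, cfg$n_outcome,
                                     cf, meta)
      fwd_rows <- lapply(seq_len(E), function(e) {
        tre <- exp_truth[[e]]
        bt <- theta_forward[e, o] * tre$gamma_true +
          sign(tre$gamma_true) * tre$alpha_true
        r <- sim_sumstats_from_truth(tre, bt, cfg$n_outcome, cf, meta)
        apply_corruptions(r, exposure_configs[[e]]$prop_allele_swapped,
                          exposure_configs[[e]]$prop_strand_flipped)
      })
      all_recs <- do.call(rbind, c(lapply(fwd_rows, as.data.frame),
                                   list(as.data.frame(own))))
      recs <- new_sumstats(all_recs, study = meta)
      emit(outcome_labels[o], "outcome", recs, meta,
           block_ld_matrix(tro, cfg$ld_within_r2), tro)
    }

    man <- do.call(rbind, manifest)
    man$n <- ifelse(man$role == "exposure",
                    vapply(exposure_configs, `[[`, 0, "n_exposure")[
                      match(man$study_id, exposure_labels)],
                    vapply(outcome_configs, `[[`, 0, "n_outcome")[
                      match(man$study_id, outcome_labels)])
    man_path <- file.path(dir, "manifest.tsv")
    utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(man, "path") <- man_path
    invisible(man)
  })
}
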