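# Orchestration of the bidirectional analysis over exposure-by-outcome
# grids: per-cell instrument selection, harmonization, estimation and
# sensitivity analysis; Bonferroni multiplicity control; the
# three-criterion robust-inference rule; report tables.

#' Bonferroni-adjusted significance threshold
#'
#' alpha / m. With 91 exposures at alpha = 0.05 this is 5.5e-4 after the
#' report's two-significant-figure rounding; with 3 it is 0.017.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (>= 1).
#' @return The threshold alpha/m.
#' @seealso [format_threshold()]
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stopf("m must be >= 1")
  alpha / m
}

#' Format a threshold at two significant figures for reports
#'
#' @param x Numeric threshold.
#' @return Character, e.g. `"5.5e-04"` or `"0.017"`.
#' @export
format_threshold <- function(x) {
  ifelse(x < 1e-3,
         formatC(signif(x, 2), format = "e", digits = 1),
         format(signif(x, 2), scientific = FALSE))
}

#' Analysis configuration for [run_direction()]
#'
#' @param p_primary,p_fallback,min_count Instrument-selection thresholds
#'   (see [select_by_pvalue()]).
#' @param clump_kb,clump_r2 LD-clumping window and r² threshold (see
#'   [clump()]).
#' @param f_min Weak-instrument cut-off (see [filter_weak()]).
#' @param ambiguity_window Palindrome frequency window (see
#'   [harmonize_pair()]).
#' @param effects_model IVW variant.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return A list of class `"mr_config"`.
#' @export
mr_config <- function(p_primary = 5e-8, p_fallback = 5e-6, min_count = 3,
                      clump_kb = 10000, clump_r2 = 0.001, f_min = 10,
                      ambiguity_window = 0.08,
                      effects_model = "multiplicative_random",
                      n_boot = 1000, seed = 1, alpha = 0.05) {
  structure(as.list(environment()), class = "mr_config")
}

#' Robust-inference call for one exposure/outcome cell
#'
#' Applies the three-criterion decision rule to a fitted cell: (1) the
#' MR-Egger intercept shows no detectable horizontal pleiotropy
#' (p > 0.05); (2) the causal estimates of all available methods agree in
#' direction, IVW remaining the designated primary estimate on
#' disagreement; (3) leave-one-out finds no outlier variant. The call is
#' robust only when all three hold. Significance tiers: `"bonferroni"`
#' when the primary p-value beats the adjusted threshold, `"suggestive"`
#' below 0.05, else `"null"`. Criteria needing an unavailable method are
#' `NA` (not evaluable).
#'
#' @param fit An [mr_fit()] object.
#' @param threshold Bonferroni-adjusted threshold for this direction.
#' @return A list of class `"causal_call"` with `primary_method`, `beta`,
#'   `pval`, `significance_tier`, `robust`, `criteria` (named:
#'   `no_pleiotropy`, `direction_consistent`, `no_loo_outlier`) and the
#'   `fit`.
#' @export
robust_call <- function(fit, threshold) {
  stopifnot(inherits(fit, "mr_fit"))
  tab <- fit$estimates
  primary_row <- match(TRUE, tab$method %in% c("ivw", "wald_ratio"))
  primary <- tab[primary_row, ]
  s <- fit$sensitivity
  no_pleio <- if (is.na(s$egger_intercept_pval)) NA else
    s$egger_intercept_pval > 0.05
  dir_cons <- if (nrow(tab) < 2) NA else
    length(unique(sign(tab$beta))) == 1
  no_loo <- if (is.na(s$loo_outlier_flag)) NA else !s$loo_outlier_flag
  robust <- no_pleio & dir_cons & no_loo
  tier <- if (primary$pval < threshold) "bonferroni"
          else if (primary$pval < 0.05) "suggestive" else "null"
  structure(
    list(primary_method = primary$method, beta = primary$beta,
         se = primary$se, pval = primary$pval,
         significance_tier = tier, robust = robust,
         criteria = c(no_pleiotropy = no_pleio,
                      direction_consistent = dir_cons,
                      no_loo_outlier = no_loo),
         threshold = threshold, fit = fit),
    class = "causal_call"
  )
}

#' @export
print.causal_call <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g, p = %.3g (threshold %s) -> %s, robust = %s\n",
              x$primary_method, x$beta, x$pval,
              format_threshold(x$threshold), x$significance_tier,
              format(x$robust)))
  invisible(x)
}

null_call <- function(reason, threshold) {
  structure(
    list(primary_method = NA_character_, beta = NA_real_, se = NA_real_,
         pval = NA_real_, significance_tier = "null", robust = NA,
         criteria = c(no_pleiotropy = NA, direction_consistent = NA,
                      no_loo_outlier = NA),
         threshold = threshold, fit = NULL, reason = reason),
    class = "causal_call"
  )
}

# One grid cell: select -> clump -> strength filter -> harmonize ->
# estimate -> sensitivity -> call.
analyze_cell <- function(exposure, outcome, exposure_id, outcome_id,
                         direction, ld, config, threshold) {
  sel <- select_by_pvalue(exposure, p_primary = config$p_primary,
                          p_fallback = config$p_fallback,
                          min_count = config$min_count)
  attrition_base <- c(candidates = nrow(exposure), selected = nrow(sel))
  if (nrow(sel)) {
    if (anyNA(sel$pos) || anyNA(sel$chrom)) {
      warnf("%s: positions missing; clumping skipped", exposure_id)
    } else {
      sel <- clump(sel, ld = ld, window_kb = config$clump_kb,
                   r2_max = config$clump_r2)
    }
  }
  iset <- instrument_set(sel, exposure_id)
  if (nrow(iset$records) && !all(is.na(iset$records$f_stat))) {
    iset <- filter_weak(iset, f_min = config$f_min)
  }
  out_meta <- attr(outcome, "study")
  outcome_type <- if (!is.null(out_meta) && out_meta$trait_type == "binary")
    "binary" else "continuous"
  pairs <- harmonize_set(iset, outcome,
                         ambiguity_window = config$ambiguity_window)
  att <- attr(pairs, "attrition")
  if (att[["analyzed"]] < 1) {
    call <- null_call("no instruments", threshold)
  } else {
    fit <- mr_fit(pairs, outcome_type = outcome_type,
                  effects_model = config$effects_model,
                  n_boot = config$n_boot, seed = config$seed)
    call <- robust_call(fit, threshold)
  }
  call$exposure_id <- exposure_id
  call$outcome_id <- outcome_id
  call$direction <- direction
  call$attrition <- c(attrition_base, att)
  call$threshold_used <- iset$threshold_used
  call
}

#' Run one direction of the analysis over an exposure-by-outcome grid
#'
#' Runs the full per-cell pipeline (p-value selection with fallback, LD
#' clumping, F-statistic filtering, harmonization, all estimators,
#' sensitivity analysis, robust-inference call) for every exposure
#' crossed with every outcome. The Bonferroni denominator is the number
#' of exposures in this direction. Cells without usable instruments yield
#' a null call with a reason rather than being dropped. A study that
#' fails to process is reported per-cell; the rest of the grid continues.
#'
#' @param exposures Named list of `"sumstats"` objects (or a manifest as
#'   read by [read_manifest()]).
#' @param outcomes Named list of `"sumstats"` objects.
#' @param config An [mr_config()].
#' @param ld Optional named list of [ld_matrix()] objects keyed by
#'   exposure id.
#' @param direction Label recorded in the calls (`"forward"` or
#'   `"reverse"`).
#' @return A list of class `"mr_calls"` of one `"causal_call"` per cell,
#'   with attribute `threshold`.
#' @export
run_direction <- function(exposures, outcomes, config = mr_config(),
                          ld = NULL, direction = "forward") {
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    stopf("exposures and outcomes must be named lists")
  }
  m <- length(exposures)
  threshold <- bonferroni_threshold(config$alpha, m)
  calls <- list()
  for (e in names(exposures)) {
    for (o in names(outcomes)) {
      call <- tryCatch(
        analyze_cell(exposures[[e]], outcomes[[o]], e, o, direction,
                     ld = ld[[e]], config = config, threshold = threshold),
        error = function(err) {
          nc <- null_call(paste("error:", conditionMessage(err)), threshold)
          nc$exposure_id <- e; nc$outcome_id <- o; nc$direction <- direction
          nc$attrition <- c(candidates = NA, selected = NA,
                            n_instruments = NA, missing_in_outcome = NA,
                            dropped_incompatible = NA,
                            dropped_ambiguous_palindrome = NA, analyzed = NA)
          nc
        }
      )
      calls[[paste(e, o, sep = "|")]] <- call
    }
  }
  structure(calls, class = "mr_calls", threshold = threshold,
            direction = direction)
}

#' Read a study manifest written by [generate_grid()]
#'
#' @param path Path to a manifest TSV (columns `study_id`, `role`,
#'   `path`, `trait_type`, `n`, `n_cases`, `n_controls`, `ld_path`).
#' @param dialect Dialect of the study files.
#' @return List with `exposures`, `outcomes` (named lists of
#'   `"sumstats"`) and `ld` (named list of LD matrices).
#' @export
read_manifest <- function(path, dialect = sumstats_dialect()) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  studies <- list(); ld <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$study_id[i]
    meta <- if (identical(man$trait_type[i], "binary")) {
      study_meta(id, trait_type = "binary", n_cases = man$n_cases[i],
                 n_controls = man$n_controls[i])
    } else {
      study_meta(id, trait_type = "continuous")
    }
    studies[[id]] <- read_sumstats(man$path[i], dialect = dialect,
                                   study = meta)
    if (!is.na(man$ld_path[i]) && nzchar(man$ld_path[i])) {
      ld[[id]] <- read_ld_matrix(man$ld_path[i])
    }
  }
  list(
    exposures = studies[man$study_id[man$role == "exposure"]],
    outcomes = studies[man$study_id[man$role == "outcome"]],
    ld = ld
  )
}

#' Build report tables from a set of causal calls
#'
#' @param calls An `"mr_calls"` list (or plain list of `"causal_call"`).
#' @return A list of data.frames: `estimates` (one row per cell and
#'   method, with odds-ratio columns for binary outcomes), `sensitivity`,
#'   `calls` (the robust-inference verdicts), `heatmap` (per-method
#'   signed -log10 p in long form) and `attrition`.
#' @export
make_reports <- function(calls) {
  empty <- function(...) {
    cols <- c(...)
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
    df
  }
  est <- list(); sens <- list(); cl <- list(); heat <- list(); attr_l <- list()
  for (call in calls) {
    base <- data.frame(exposure = call$exposure_id,
                       outcome = call$outcome_id,
                       direction = call$direction, stringsAsFactors = FALSE)
    cl[[length(cl) + 1]] <- cbind(base, data.frame(
      method = call$primary_method, beta = call$beta, se = call$se,
      pval = call$pval, threshold = call$threshold,
      significance_tier = call$significance_tier,
      robust = call$robust,
      no_pleiotropy = call$criteria[["no_pleiotropy"]],
      direction_consistent = call$criteria[["direction_consistent"]],
      no_loo_outlier = call$criteria[["no_loo_outlier"]],
      reason = call$reason %||% NA_character_, stringsAsFactors = FALSE))
    if (!is.null(call$attrition)) {
      attr_l[[length(attr_l) + 1]] <-
        cbind(base, as.data.frame(as.list(call$attrition)))
    }
    fit <- call$fit
    if (is.null(fit)) next
    tab <- fit$estimates
    if (!"or" %in% names(tab)) tab$or <- tab$or_low <- tab$or_high <- NA_real_
    est[[length(est) + 1]] <- cbind(base[rep(1, nrow(tab)), , drop = FALSE],
                                    tab)
    s <- fit$sensitivity
    sens[[length(sens) + 1]] <- cbind(base, data.frame(
      q = s$q, q_df = s$q_df, q_pval = s$q_pval,
      egger_intercept = s$egger_intercept,
      egger_intercept_se = s$egger_intercept_se,
      egger_intercept_pval = s$egger_intercept_pval,
      loo_outlier_flag = s$loo_outlier_flag, stringsAsFactors = FALSE))
    heat[[length(heat) + 1]] <- cbind(
      base[rep(1, nrow(tab)), , drop = FALSE],
      data.frame(method = tab$method,
                 signed_log10p = -log10(tab$pval) * sign(tab$beta),
                 stringsAsFactors = FALSE))
  }
  bind <- function(lst, ...) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else empty(...)
  }
  list(
    estimates = bind(est, "exposure", "outcome", "direction", "method",
                     "n_snp", "beta", "se", "ci_low", "ci_high", "pval",
                     "or", "or_low", "or_high"),
    sensitivity = bind(sens, "exposure", "outcome", "direction", "q",
                       "q_df", "q_pval", "egger_intercept",
                       "egger_intercept_se", "egger_intercept_pval",
                       "loo_outlier_flag"),
    calls = bind(cl, "exposure", "outcome", "direction", "method", "beta",
                 "se", "pval", "threshold", "significance_tier", "robust",
                 "no_pleiotropy", "direction_consistent", "no_loo_outlier",
                 "reason"),
    heatmap = bind(heat, "exposure", "outcome", "direction", "method",
                   "signed_log10p"),
    attrition = bind(attr_l, "exposure", "outcome", "direction")
  )
}

#' Write report tables as TSV files
#'
#' Writes `estimates.tsv`, `sensitivity.tsv`, `calls.tsv`, `heatmap.tsv`
#' and `attrition.tsv` to `dir`. Numeric columns are serialized with
#' full precision so identical analyses produce byte-identical files.
#'
#' @param reports Output of [make_reports()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(reports)) {
    df <- reports[[name]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
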