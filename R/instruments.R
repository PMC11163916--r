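# Instrument selection for one exposure: p-value thresholding with a
# fallback threshold, greedy LD clumping, per-variant variance explained
# and F-statistics, and weak-instrument exclusion.

#' Select genome-wide significant variants with a fallback threshold
#'
#' Variants passing the primary threshold (5e-8) are used when at least
#' `min_count` of them exist; otherwise the relaxed fallback threshold
#' (5e-6) is applied, so exposures with few strong signals still yield
#' enough instruments for the pleiotropy-robust estimators.
#'
#' @param records A `"sumstats"` data.frame.
#' @param p_primary Primary genome-wide significance threshold.
#' @param p_fallback Relaxed threshold used when the primary yields fewer
#'   than `min_count` variants.
#' @param min_count Minimum variant count before falling back. Default 3,
#'   the smallest set admitting MR-Egger.
#' @return The selected records with attribute `threshold_used` (one of
#'   `p_primary`, `p_fallback`).
#' @export
select_by_pvalue <- function(records, p_primary = 5e-8, p_fallback = 5e-6,
                             min_count = 3) {
  pass_primary <- records$pval < p_primary
  if (sum(pass_primary) >= min_count) {
    out <- records[pass_primary, , drop = FALSE]
    thr <- p_primary
  } else {
    pass <- records$pval < p_fallback
    out <- records[pass, , drop = FALSE]
    thr <- p_fallback
    if (!nrow(out)) {
      warnf("no variants pass either threshold (%.0e, %.0e)",
            p_primary, p_fallback)
    }
  }
  rownames(out) <- NULL
  attr(out, "threshold_used") <- thr
  class(out) <- class(records)
  out
}

#' Construct an LD matrix object
#'
#' @param r2 Square numeric matrix of squared correlations, unit diagonal.
#' @param variant_ids Variant identifiers (taken from `dimnames(r2)` when
#'   omitted).
#' @return A matrix of class `"ld_matrix"`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stopf("LD matrix needs variant ids")
  dimnames(r2) <- list(variant_ids, variant_ids)
  if (nrow(r2) != ncol(r2)) stopf("LD matrix must be square")
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stopf("r2 entries must lie in [0,1]")
  if (any(abs(diag(r2) - 1) > 1e-12)) stopf("LD matrix diagonal must be 1")
  if (max(abs(r2 - t(r2))) > 1e-8) stopf("LD matrix must be symmetric")
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from file
#'
#' Accepts either a square TSV with variant ids as header row and first
#' column, or long-format triplets with columns `id1`, `id2`, `r2`
#' (missing pairs default to 0).
#'
#' @param path TSV path.
#' @return An `"ld_matrix"`.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (identical(sort(names(df)), sort(c("id1", "id2", "r2")))) {
    ids <- unique(c(df$id1, df$id2))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(df$id1, ids); j <- match(df$id2, ids)
    m[cbind(i, j)] <- df$r2
    m[cbind(j, i)] <- df$r2
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  ld_matrix(m)
}

#' Write an LD matrix as a square TSV
#'
#' @param ld An `"ld_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(variant_id = rownames(ld),
                   as.data.frame(unclass(ld), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index (ties broken lexicographically by `variant_id` for determinism)
#' and removes every other variant on the same chromosome within
#' `window_kb` kilobases whose squared correlation with the index is at
#' least `r2_max`. Pairs absent from `ld` are treated as r² = 0 with a
#' warning.
#'
#' @param records A `"sumstats"` data.frame with `chrom` and `pos`.
#' @param ld An [ld_matrix()] covering the clumped variants (or `NULL` for
#'   no LD information, i.e. all pairs independent).
#' @param window_kb Window in kilobases (default 10,000).
#' @param r2_max Squared-correlation threshold (default 0.001).
#' @return The index variants, sorted by chromosome then position, with
#'   attribute `clump_log` recording removals.
#' @export
clump <- function(records, ld = NULL, window_kb = 10000, r2_max = 0.001) {
  if (!nrow(records)) return(records)
  if (anyNA(records$pos) || anyNA(records$chrom)) {
    bad <- records$variant_id[is.na(records$pos) | is.na(records$chrom)]
    stopf("clumping requires chrom/pos; missing for: %s",
          paste(bad, collapse = ", "))
  }
  ids <- records$variant_id
  ld_lookup <- function(i, j) {
    if (is.null(ld)) return(0)
    a <- ids[i]; b <- ids[j]
    if (a %in% rownames(ld) && b %in% rownames(ld)) return(ld[a, b])
    warnf("LD pair (%s, %s) not in matrix; assuming r2 = 0", a, b)
    0
  }
  # deterministic greedy order: pval, then lexicographic id
  order_idx <- order(records$pval, records$variant_id)
  alive <- rep(TRUE, nrow(records))
  index <- logical(nrow(records))
  log <- list()
  for (i in order_idx) {
    if (!alive[i]) next
    index[i] <- TRUE
    for (j in seq_len(nrow(records))) {
      if (j == i || !alive[j]) next
      if (records$chrom[j] != records$chrom[i]) next
      if (abs(records$pos[j] - records$pos[i]) > window_kb * 1000) next
      if (ld_lookup(i, j) >= r2_max) {
        alive[j] <- FALSE
        log[[length(log) + 1]] <- data.frame(
          variant_id = ids[j], action = "removed_ld",
          detail = sprintf("r2>=%g with index %s", r2_max, ids[i]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- records[index, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold_used") <- attr(records, "threshold_used")
  attr(out, "clump_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(), action = character(),
               detail = character())
  class(out) <- class(records)
  out
}

#' Variance in the exposure explained by one variant
#'
#' R² = 2·MAF·(1−MAF)·β², with MAF the minor-allele frequency
#' `min(eaf, 1−eaf)`. Assumes `beta` is on the standardized (per-SD) scale.
#'
#' @param eaf Effect-allele frequency in (0,1).
#' @param beta Per-allele effect size.
#' @return The explained variance proportion, capped just below 1.
#' @export
#' @examples
#' variance_explained(0.9, 0.2)  # 2 * 0.1 * 0.9 * 0.04 = 0.0072
variance_explained <- function(eaf, beta) {
  if (any(is.na(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stopf("eaf must lie strictly in (0,1)")
  }
  maf <- pmin(eaf, 1 - eaf)
  r2 <- 2 * maf * (1 - maf) * beta^2
  if (any(r2 >= 1)) {
    warnf("variance explained >= 1 for %d variant(s); capping", sum(r2 >= 1))
    r2 <- pmin(r2, 1 - 1e-12)
  }
  r2
}

#' Instrument-strength F-statistic
#'
#' F = R²/(1−R²) · (n−k−1)/k. Per-variant strength uses k = 1 with that
#' variant's R²; the aggregate over an instrument set uses k = number of
#' instruments with R² the sum of per-variant values.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size of the exposure GWAS.
#' @param k Number of instruments (1 for per-variant strength).
#' @return The F-statistic.
#' @export
#' @examples
#' f_statistic(0.0072, 14824, 1)  # about 107.5
f_statistic <- function(r2, n, k = 1) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    stopf("r2 must lie in [0,1)")
  }
  if (any(is.na(n)) || any(n <= k + 1)) stopf("need n > k + 1")
  r2 / (1 - r2) * (n - k - 1) / k
}

#' Assemble an instrument set with strength statistics
#'
#' Computes per-variant R² and F (k = 1) and the aggregate F (k = number of
#' instruments, R² summed and capped below 1) for an exposure's selected,
#' clumped variants.
#'
#' @param records Selected records (output of [select_by_pvalue()] /
#'   [clump()]).
#' @param exposure_id Exposure identifier.
#' @param n Exposure sample size; defaults to the per-record `n` column.
#' @return A list of class `"instrument_set"` with elements `exposure_id`,
#'   `records` (with `r2_explained`, `f_stat` columns), `threshold_used`,
#'   `aggregate_f`, `selection_log`.
#' @export
instrument_set <- function(records, exposure_id, n = NULL) {
  recs <- as.data.frame(records)
  n_eff <- if (!is.null(n)) rep(n, length.out = nrow(recs)) else recs$n
  if (!is.null(n)) recs$n <- n_eff
  if (nrow(recs)) {
    if (anyNA(recs$eaf)) {
      warnf("exposure %s: missing eaf for %d variant(s); R2/F unavailable",
            exposure_id, sum(is.na(recs$eaf)))
    }
    have <- !is.na(recs$eaf) & !is.na(n_eff)
    recs$r2_explained <- NA_real_
    recs$f_stat <- NA_real_
    if (any(have)) {
      recs$r2_explained[have] <- variance_explained(recs$eaf[have],
                                                    recs$beta[have])
      recs$f_stat[have] <- f_statistic(recs$r2_explained[have],
                                       n_eff[have], k = 1)
    }
  } else {
    recs$r2_explained <- numeric()
    recs$f_stat <- numeric()
  }
  agg <- NA_real_
  if (nrow(recs) && !anyNA(recs$r2_explained) && !anyNA(n_eff)) {
    r2_sum <- min(sum(recs$r2_explained), 1 - 1e-12)
    k <- nrow(recs)
    n_min <- min(n_eff)
    if (n_min > k + 1) agg <- f_statistic(r2_sum, n_min, k = k)
  }
  structure(
    list(exposure_id = exposure_id, records = recs,
         threshold_used = attr(records, "threshold_used"),
         aggregate_f = agg,
         selection_log = data.frame(variant_id = character(),
                                    stage = character(), action = character(),
                                    detail = character())),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d variants (threshold %s)\n",
              x$exposure_id, nrow(x$records),
              format(x$threshold_used %||% NA)))
  if (nrow(x$records) && !anyNA(x$records$f_stat)) {
    cat(sprintf("  per-variant F: %.2f - %.2f; aggregate F (k=%d): %.2f\n",
                min(x$records$f_stat), max(x$records$f_stat),
                nrow(x$records), x$aggregate_f))
  }
  invisible(x)
}

#' Drop weak instruments
#'
#' Removes variants whose per-variant F-statistic falls below `f_min`
#' (default 10, the conventional weak-instrument cut-off). Variants whose F
#' could not be computed (missing eaf or n) are retained with a warning.
#'
#' @param iset An `"instrument_set"`.
#' @param f_min Minimum per-variant F.
#' @return The filtered instrument set; removals appended to
#'   `selection_log`.
#' @export
filter_weak <- function(iset, f_min = 10) {
  recs <- iset$records
  if (!nrow(recs)) return(iset)
  f <- recs$f_stat
  weak <- !is.na(f) & f < f_min
  if (any(is.na(f))) {
    warnf("exposure %s: F unavailable for %d variant(s); kept unfiltered",
          iset$exposure_id, sum(is.na(f)))
  }
  if (all(weak)) warnf("exposure %s: all instruments weak (F < %g)",
                       iset$exposure_id, f_min)
  if (any(weak)) {
    iset$selection_log <- rbind(iset$selection_log, data.frame(
      variant_id = recs$variant_id[weak], stage = "filter_weak",
      action = "removed_weak",
      detail = sprintf("F=%.3f < %g", f[weak], f_min),
      stringsAsFactors = FALSE
    ))
  }
  iset$records <- recs[!weak, , drop = FALSE]
  rownames(iset$records) <- NULL
  # aggregate F changes with the retained set
  if (nrow(iset$records) && !anyNA(iset$records$r2_explained) &&
      !anyNA(iset$records$n)) {
    r2_sum <- min(sum(iset$records$r2_explained), 1 - 1e-12)
    k <- nrow(iset$records)
    n_min <- min(iset$records$n)
    iset$aggregate_f <- if (n_min > k + 1) f_statistic(r2_sum, n_min, k) else NA_real_
  } else {
    iset$aggregate_f <- NA_real_
  }
  iset
}
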