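# Allele harmonization: place each exposure/outcome variant pair on a
# common effect allele, resolving strand flips by complementing and
# palindromic ambiguity by allele frequency, and dropping pairs that
# cannot be reconciled.

HARMONIZE_ACTIONS <- c(
  "kept", "sign_flipped", "strand_flipped", "strand_flipped_and_sign_flipped",
  "dropped_incompatible", "dropped_ambiguous_palindrome"
)

#' Harmonize one exposure/outcome record pair onto a common effect allele
#'
#' Non-palindromic pairs are aligned by allele labels, complementing the
#' outcome's alleles when they sit on the opposite strand; a swapped
#' orientation flips the sign of the outcome effect and reflects its
#' frequency. Palindromic pairs (A/T, G/C) carry no strand information in
#' their labels, so orientation is inferred from allele frequencies: the
#' pair is dropped when either frequency is missing or both lie within the
#' ambiguity window around 0.5, and otherwise oriented so both studies'
#' frequencies fall on the same side of 0.5.
#'
#' @param exp_rec,out_rec Single-row summary-statistic records (lists or
#'   one-row data.frames) for the same `variant_id`.
#' @param ambiguity_window Half-width of the frequency window around 0.5
#'   within which a palindromic pair is considered unresolvable
#'   (default 0.08, i.e. drop when both frequencies are in \[0.42, 0.58\]).
#' @return A one-row data.frame with columns `variant_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `action`.
#'   Dropped pairs carry `NA` effects and a `dropped_*` action.
#' @export
harmonize_pair <- function(exp_rec, out_rec, ambiguity_window = 0.08) {
  if (!identical(as.character(exp_rec$variant_id),
                 as.character(out_rec$variant_id))) {
    stopf("variant_id mismatch: %s vs %s",
          exp_rec$variant_id, out_rec$variant_id)
  }
  ea_x <- exp_rec$effect_allele; oa_x <- exp_rec$other_allele
  ea_y <- out_rec$effect_allele; oa_y <- out_rec$other_allele
  beta_y <- out_rec$beta; eaf_y <- out_rec$eaf
  eaf_x <- exp_rec$eaf

  result <- function(action, beta_out = NA_real_, eaf_out = NA_real_) {
    data.frame(
      variant_id = as.character(exp_rec$variant_id),
      beta_exp = if (startsWith(action, "dropped")) NA_real_ else exp_rec$beta,
      se_exp = exp_rec$se,
      beta_out = beta_out, se_out = out_rec$se,
      eaf_exp = if (is.null(eaf_x)) NA_real_ else eaf_x,
      eaf_out = eaf_out,
      action = action, stringsAsFactors = FALSE
    )
  }

  if (is_palindromic(ea_x, oa_x)) {
    # outcome labels must be the same complementary pair
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)) || !is_palindromic(ea_y, oa_y)) {
      return(result("dropped_incompatible"))
    }
    if (is.null(eaf_x) || is.na(eaf_x) || is.null(eaf_y) || is.na(eaf_y)) {
      return(result("dropped_ambiguous_palindrome"))
    }
    lo <- 0.5 - ambiguity_window; hi <- 0.5 + ambiguity_window
    if (eaf_x >= lo && eaf_x <= hi && eaf_y >= lo && eaf_y <= hi) {
      return(result("dropped_ambiguous_palindrome"))
    }
    label_swap <- ea_y == oa_x  # nominal orientation differs
    if (label_swap) {
      beta_y <- -beta_y
      eaf_y <- 1 - eaf_y
    }
    freq_flip <- (eaf_x < 0.5) != (eaf_y < 0.5)  # opposite sides of 0.5
    if (freq_flip) {
      beta_y <- -beta_y
      eaf_y <- 1 - eaf_y
    }
    action <- if (label_swap && freq_flip) "strand_flipped"
      else if (label_swap) "sign_flipped"
      else if (freq_flip) "strand_flipped_and_sign_flipped"
      else "kept"
    return(result(action, beta_out = beta_y, eaf_out = eaf_y))
  }

  # non-palindromic: try as-is, then on the complementary strand
  strand_flip <- FALSE
  if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
    ea_y <- complement_allele(ea_y)
    oa_y <- complement_allele(oa_y)
    strand_flip <- TRUE
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(result("dropped_incompatible"))
    }
  }
  if (ea_y == ea_x) {
    action <- if (strand_flip) "strand_flipped" else "kept"
  } else {
    beta_y <- -beta_y
    if (!is.null(eaf_y) && !is.na(eaf_y)) eaf_y <- 1 - eaf_y
    action <- if (strand_flip) "strand_flipped_and_sign_flipped"
              else "sign_flipped"
  }
  result(action, beta_out = beta_y,
         eaf_out = if (is.null(eaf_y)) NA_real_ else eaf_y)
}

#' Harmonize an instrument set against outcome summary statistics
#'
#' Matches instruments to outcome records by `variant_id`, harmonizes each
#' pair with [harmonize_pair()], and tabulates attrition. Pairs dropped as
#' incompatible or as unresolvable palindromes are excluded from the
#' analyzed set but counted.
#'
#' @param iset An [instrument_set()] (or a `"sumstats"` data.frame of
#'   exposure records).
#' @param outcome_records A `"sumstats"` data.frame for the outcome.
#' @param ambiguity_window Passed to [harmonize_pair()].
#' @return A data.frame of class `"harmonized_pairs"` (analyzed pairs only)
#'   with attributes `attrition` (named counts `n_instruments`,
#'   `missing_in_outcome`, `dropped_incompatible`,
#'   `dropped_ambiguous_palindrome`, `analyzed`) and `audit` (per-variant
#'   action table).
#' @export
harmonize_set <- function(iset, outcome_records, ambiguity_window = 0.08) {
  exp_recs <- if (inherits(iset, "instrument_set")) iset$records
              else as.data.frame(iset)
  out_recs <- as.data.frame(outcome_records)
  n_inst <- nrow(exp_recs)
  idx <- match(exp_recs$variant_id, out_recs$variant_id)
  missing <- is.na(idx)
  rows <- vector("list", n_inst)
  for (i in which(!missing)) {
    rows[[i]] <- harmonize_pair(exp_recs[i, , drop = FALSE],
                                out_recs[idx[i], , drop = FALSE],
                                ambiguity_window = ambiguity_window)
  }
  all_pairs <- if (any(!missing)) do.call(rbind, rows[!missing]) else
    data.frame(variant_id = character(), beta_exp = numeric(),
               se_exp = numeric(), beta_out = numeric(), se_out = numeric(),
               eaf_exp = numeric(), eaf_out = numeric(), action = character(),
               stringsAsFactors = FALSE)
  dropped_inc <- sum(all_pairs$action == "dropped_incompatible")
  dropped_pal <- sum(all_pairs$action == "dropped_ambiguous_palindrome")
  analyzed <- all_pairs[!startsWith(all_pairs$action, "dropped"), ,
                        drop = FALSE]
  rownames(analyzed) <- NULL
  attrition <- c(
    n_instruments = n_inst,
    missing_in_outcome = sum(missing),
    dropped_incompatible = dropped_inc,
    dropped_ambiguous_palindrome = dropped_pal,
    analyzed = nrow(analyzed)
  )
  structure(analyzed,
            class = c("harmonized_pairs", "data.frame"),
            attrition = attrition,
            audit = all_pairs[, c("variant_id", "action",
                                  "eaf_exp", "eaf_out")])
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  att <- attr(x, "attrition")
  cat(sprintf("Harmonized pairs: %d analyzed of %d instruments\n",
              att[["analyzed"]], att[["n_instruments"]]))
  cat(sprintf(
    "  missing in outcome: %d; incompatible: %d; ambiguous palindrome: %d\n",
    att[["missing_in_outcome"]], att[["dropped_incompatible"]],
    att[["dropped_ambiguous_palindrome"]]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write the harmonization audit table
#'
#' @param pairs A `"harmonized_pairs"` object.
#' @param path Output TSV path (columns `variant_id`, `action`, `eaf_exp`,
#'   `eaf_out`).
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(pairs, path) {
  utils::write.table(attr(pairs, "audit"), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
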