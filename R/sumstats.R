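# Reading, validating and writing GWAS summary-statistic tables.
#
# Canonical in-memory representation: a data.frame of class "sumstats" with
# columns variant_id, chrom, pos, effect_allele, other_allele, eaf, beta,
# se, pval, n (chrom/pos/eaf/n may be NA). Study-level metadata and the
# reject log travel as attributes.

SUMSTAT_COLUMNS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)
REQUIRED_COLUMNS <- c(
  "variant_id", "effect_allele", "other_allele", "beta", "se", "pval"
)

#' Describe the file dialect of a summary-statistic table
#'
#' A dialect maps the canonical column names used internally to the physical
#' column names of a particular file, and fixes the delimiter, the missing
#' token and the zero-p-value policy. Columns `chrom`, `pos`, `eaf` and `n`
#' are optional; dropping one disables the downstream step that needs it
#' (clumping needs positions, palindrome resolution needs frequencies, the
#' F-statistic needs sample sizes).
#'
#' @param variant_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n
#'   Physical column names; pass `NULL` for an optional column absent from
#'   the file.
#' @param sep Field delimiter; `"\t"` (default) or `","`.
#' @param na Missing-value token used on disk.
#' @param pval_floor If `TRUE`, rows with `pval == 0` are clamped to the
#'   smallest positive double and flagged instead of rejected.
#' @return A list of class `"sumstats_dialect"`.
#' @seealso [read_sumstats()], [write_sumstats()], [read_dialect()]
#' @export
sumstats_dialect <- function(variant_id = "variant_id", chrom = "chrom",
                             pos = "pos", effect_allele = "effect_allele",
                             other_allele = "other_allele", eaf = "eaf",
                             beta = "beta", se = "se", pval = "pval",
                             n = "n", sep = "\t", na = "NA",
                             pval_floor = FALSE) {
  map <- list(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n
  )
  missing_req <- REQUIRED_COLUMNS[vapply(map[REQUIRED_COLUMNS], is.null, logical(1))]
  if (length(missing_req)) {
    stopf("dialect must map required column(s): %s",
          paste(missing_req, collapse = ", "))
  }
  structure(
    list(map = map, sep = sep, na = na, pval_floor = isTRUE(pval_floor)),
    class = "sumstats_dialect"
  )
}

#' Read a dialect definition from a YAML or JSON config file
#'
#' The file holds a mapping with a `columns` block (canonical name ->
#' physical name) and optional `sep`, `na`, `pval_floor` entries.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"sumstats_dialect"` object.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) stopf("dialect file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cols <- as.list(cfg$columns %||% list())
  args <- cols[intersect(names(cols), SUMSTAT_COLUMNS)]
  for (opt in setdiff(SUMSTAT_COLUMNS, REQUIRED_COLUMNS)) {
    if (!opt %in% names(cols)) args[[opt]] <- list(NULL)  # absent -> NULL
  }
  args <- lapply(args, function(x) if (is.list(x)) NULL else x)
  do.call(sumstats_dialect, c(args, list(
    sep = cfg$sep %||% "\t", na = cfg$na %||% "NA",
    pval_floor = isTRUE(cfg$pval_floor)
  )))
}

#' Study-level metadata for a summary-statistic table
#'
#' @param study_id Short unique identifier.
#' @param trait_name Human-readable trait name.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits require
#'   `n_cases` and `n_controls`.
#' @param n_cases,n_controls Case/control counts for binary traits.
#' @param ancestry_label Free-text ancestry description.
#' @return A list of class `"study_meta"`.
#' @export
study_meta <- function(study_id, trait_name = study_id,
                       trait_type = c("continuous", "binary"),
                       n_cases = NULL, n_controls = NULL,
                       ancestry_label = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary" && (is.null(n_cases) || is.null(n_controls))) {
    stopf("binary trait '%s' requires n_cases and n_controls", study_id)
  }
  structure(
    list(study_id = study_id, trait_name = trait_name,
         trait_type = trait_type, n_cases = n_cases,
         n_controls = n_controls, ancestry_label = ancestry_label),
    class = "study_meta"
  )
}

new_sumstats <- function(df, study = NULL, rejects = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            study = study,
            rejects = rejects %||%
              data.frame(row_number = integer(), reason = character()))
}

#' @export
print.sumstats <- function(x, ...) {
  st <- attr(x, "study")
  if (!is.null(st)) {
    cat(sprintf("GWAS summary statistics: %s (%s)\n",
                st$trait_name, st$trait_type))
  } else {
    cat("GWAS summary statistics\n")
  }
  cat(sprintf("  %d variants, %d rejected rows\n",
              nrow(x), nrow(attr(x, "rejects"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# Row-wise validation. Returns list(records, rejects); every input row lands
# in exactly one of the two so counts always reconcile.
validate_sumstats <- function(df, pval_floor = FALSE) {
  n_in <- nrow(df)
  reason <- rep(NA_character_, n_in)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }

  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$variant_id <- as.character(df$variant_id)

  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant_id")
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(!ok_allele(df$effect_allele) | !ok_allele(df$other_allele),
       "invalid allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta) | !is.finite(df$beta), "missing beta")
  flag(is.na(df$se) | !is.finite(df$se) | df$se <= 0, "non-positive se")
  if (pval_floor) {
    clamp <- !is.na(df$pval) & df$pval == 0
    df$pval[clamp] <- .Machine$double.xmin
  } else {
    clamp <- rep(FALSE, n_in)
  }
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  flag(!is.na(df$n) & df$n <= 0, "non-positive n")
  flag(!is.na(df$pos) & df$pos < 1, "non-positive position")

  keep <- is.na(reason)
  records <- df[keep, SUMSTAT_COLUMNS, drop = FALSE]
  records$pval_floored <- clamp[keep]
  rejects <- data.frame(
    row_number = which(!keep),
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  list(records = records, rejects = rejects)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (transparently gzipped) through a column
#' dialect, validates every row, and returns the clean records. Validation
#' is total: each input row becomes either a record or an entry in the
#' reject log (`attr(x, "rejects")`), with row counts reconciling.
#'
#' @param path File path; `.gz` files are decompressed transparently.
#' @param dialect A [sumstats_dialect()] describing the file layout.
#' @param study Optional [study_meta()] attached to the result.
#' @return A `"sumstats"` data.frame with attributes `study` and `rejects`
#'   (a data.frame of `row_number`, `reason`).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), study = NULL) {
  if (!inherits(dialect, "sumstats_dialect")) {
    stopf("`dialect` must be a sumstats_dialect object")
  }
  if (!file.exists(path)) stopf("cannot read summary statistics: %s", path)
  raw <- utils::read.table(
    gzfile(path), header = TRUE, sep = dialect$sep,
    na.strings = dialect$na, stringsAsFactors = FALSE,
    check.names = FALSE, comment.char = "", quote = "\""
  )
  map <- dialect$map
  present <- !vapply(map, is.null, logical(1))
  physical <- unlist(map[present])
  missing_cols <- physical[!physical %in% names(raw)]
  if (length(missing_cols)) {
    stopf("file %s lacks mapped column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  cols <- lapply(SUMSTAT_COLUMNS, function(canon) {
    if (!is.null(map[[canon]])) raw[[map[[canon]]]] else rep(NA, nrow(raw))
  })
  df <- as.data.frame(stats::setNames(cols, SUMSTAT_COLUMNS),
                      stringsAsFactors = FALSE)
  df$pos <- suppressWarnings(as.integer(df$pos))
  for (num in c("eaf", "beta", "se", "pval", "n")) {
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  }
  df$chrom <- as.character(df$chrom)
  v <- validate_sumstats(df, pval_floor = dialect$pval_floor)
  new_sumstats(v$records, study = study, rejects = v$rejects)
}

#' Write a summary-statistic table in a given dialect
#'
#' Inverse of [read_sumstats()]: writing then reading reproduces the records
#' field-for-field. Missing values are serialized as the dialect's missing
#' token; a `.gz` path writes gzip output.
#'
#' @param records A `"sumstats"` data.frame (or compatible data.frame).
#' @param path Output path.
#' @param dialect A [sumstats_dialect()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path, dialect = sumstats_dialect()) {
  map <- dialect$map
  present <- names(map)[!vapply(map, is.null, logical(1))]
  out <- as.data.frame(records)[, present, drop = FALSE]
  names(out) <- unlist(map[present])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = dialect$sep, na = dialect$na,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the reject log of a summary-statistic table
#'
#' @param x A `"sumstats"` object.
#' @param path Output TSV path (columns `row_number`, `reason`).
#' @return `path`, invisibly.
#' @export
write_reject_log <- function(x, path) {
  utils::write.table(attr(x, "rejects"), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate variant records
#'
#' Keeps one record per `variant_id`: the one with the smallest p-value;
#' p-value ties keep the first-encountered record. Actions are recorded in
#' `attr(x, "dedup_log")`.
#'
#' @param records A `"sumstats"` data.frame.
#' @return The deduplicated records, original relative order preserved.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  # stable order by pval within variant_id; first row per id is the keeper
  ord <- order(records$variant_id, records$pval)
  first <- !duplicated(records$variant_id[ord])
  keep_rows <- sort(ord[first])
  dropped <- setdiff(seq_len(nrow(records)), keep_rows)
  log <- data.frame(
    variant_id = records$variant_id[dropped],
    action = rep("dropped_duplicate", length(dropped)),
    stringsAsFactors = FALSE
  )
  dup_ids <- unique(records$variant_id[dropped])
  if (length(dup_ids)) {
    tied <- vapply(dup_ids, function(id) {
      p <- records$pval[records$variant_id == id]
      anyDuplicated(p[p == min(p)]) > 0 || sum(p == min(p)) > 1
    }, logical(1))
    if (any(tied)) {
      log <- rbind(log, data.frame(variant_id = dup_ids[tied],
                                   action = "tie_kept_first",
                                   stringsAsFactors = FALSE))
    }
  }
  out <- records[keep_rows, , drop = FALSE]
  attr(out, "study") <- attr(records, "study")
  attr(out, "rejects") <- attr(records, "rejects")
  attr(out, "dedup_log") <- log
  class(out) <- class(records)
  rownames(out) <- NULL
  out
}
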