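# The user-facing model object: fit all applicable MR estimators to a set
# of harmonized pairs and bundle them with the sensitivity analysis.

#' Fit two-sample MR estimators to harmonized variant pairs
#'
#' Fits every estimator the instrument count admits — Wald ratio for a
#' single variant, IVW for two or more, MR-Egger and the weighted median
#' for three or more — together with the sensitivity battery (Cochran's Q
#' against the IVW estimate, the Egger intercept test, leave-one-out).
#' IVW is the designated primary estimate.
#'
#' @param pairs A `"harmonized_pairs"` data.frame (see [harmonize_set()]),
#'   or any data.frame with columns `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` (and optionally `variant_id`).
#' @param outcome_type `"binary"` adds odds-ratio columns (`exp(beta)` and
#'   bounds) to the estimates table; `"continuous"` reports beta/SE only.
#' @param effects_model IVW variant: `"multiplicative_random"` (default)
#'   or `"fixed"`.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return An object of class `"mr_fit"`: a list with `estimates` (a
#'   data.frame, one row per method), `sensitivity` (Q, Egger intercept
#'   test, leave-one-out table and outlier flag), `pairs`, `n_snp`,
#'   `outcome_type`.
#' @export
#' @examples
#' pairs <- data.frame(
#'   variant_id = paste0("rs", 1:5),
#'   beta_exp = c(0.12, 0.10, 0.15, 0.09, 0.11), se_exp = 0.01,
#'   beta_out = c(0.024, 0.020, 0.030, 0.018, 0.022), se_out = 0.01
#' )
#' fit <- mr_fit(pairs, outcome_type = "binary")
#' fit
#' coef(fit)
mr_fit <- function(pairs, outcome_type = c("continuous", "binary"),
                   effects_model = c("multiplicative_random", "fixed"),
                   n_boot = 1000, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  effects_model <- match.arg(effects_model)
  p <- as_pairs_df(pairs)
  n <- nrow(p)
  if (n < 1) stopf("mr_fit needs at least one harmonized pair")

  ests <- list()
  if (n == 1) {
    ests$wald_ratio <- wald_ratio(p)
  } else {
    ests$ivw <- ivw(p, effects_model = effects_model)
  }
  egger <- NULL
  if (n >= 3) {
    egger <- mr_egger(p)
    ests$mr_egger <- egger$slope
    ests$weighted_median <- weighted_median(p, n_boot = n_boot, seed = seed)
  }

  sens <- list(q = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_pval = NA_real_,
               loo_table = NULL, loo_outlier_flag = NA)
  if (n >= 2) {
    qres <- cochran_q(p, ests$ivw$beta)
    sens[c("q", "q_df", "q_pval")] <- qres
  }
  if (!is.null(egger)) {
    sens$egger_intercept <- egger$intercept
    sens$egger_intercept_se <- egger$intercept_se
    sens$egger_intercept_pval <- egger$intercept_pval
  }
  if (n >= 3) {
    loo <- leave_one_out(p, effects_model = effects_model)
    sens$loo_table <- loo$loo_table
    sens$loo_outlier_flag <- loo$loo_outlier_flag
  }

  tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (outcome_type == "binary") {
    orr <- to_odds_ratio(tab$beta, tab$se)
    tab$or <- orr$or
    tab$or_low <- exp(tab$ci_low)
    tab$or_high <- exp(tab$ci_high)
  }

  structure(
    list(estimates = tab, sensitivity = sens, pairs = p, n_snp = n,
         outcome_type = outcome_type, effects_model = effects_model,
         primary_method = tab$method[1]),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %d instrument(s), %s outcome\n",
              x$n_snp, x$outcome_type))
  print.data.frame(format(x$estimates, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", class(object)))
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print.mr_fit(x, digits = digits)
  s <- x$sensitivity
  cat("\nSensitivity analysis:\n")
  if (!is.na(s$q)) {
    cat(sprintf("  Cochran's Q = %.4g on %d df, p = %.3g\n",
                s$q, s$q_df, s$q_pval))
  }
  if (!is.na(s$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (se %.4g), p = %.3g\n",
                s$egger_intercept, s$egger_intercept_se,
                s$egger_intercept_pval))
  }
  if (!is.null(s$loo_table)) {
    cat(sprintf("  Leave-one-out outlier flag: %s\n", s$loo_outlier_flag))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && abs(level - 0.95) > 1e-12) {
    stopf("only 95%% intervals are computed")
  }
  m <- as.matrix(object$estimates[, c("ci_low", "ci_high")])
  rownames(m) <- object$estimates$method
  colnames(m) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Scatter plot of variant effects with fitted causal slopes
#'
#' @param x An `"mr_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$pairs
  graphics::plot(p$beta_exp, p$beta_out,
                 xlab = "variant effect on exposure (SD)",
                 ylab = "variant effect on outcome",
                 pch = 19, ...)
  graphics::segments(p$beta_exp, p$beta_out - Z95 * p$se_out,
                     p$beta_exp, p$beta_out + Z95 * p$se_out,
                     col = "grey60")
  graphics::segments(p$beta_exp - Z95 * p$se_exp, p$beta_out,
                     p$beta_exp + Z95 * p$se_exp, p$beta_out,
                     col = "grey60")
  cols <- c(ivw = "black", mr_egger = "firebrick",
            weighted_median = "steelblue", wald_ratio = "black")
  for (i in seq_len(nrow(x$estimates))) {
    m <- x$estimates$method[i]
    intercept <- if (m == "mr_egger") x$sensitivity$egger_intercept else 0
    graphics::abline(intercept, x$estimates$beta[i],
                     col = cols[[m]], lty = i)
  }
  graphics::legend("topleft", legend = x$estimates$method,
                   col = cols[x$estimates$method],
                   lty = seq_len(nrow(x$estimates)), bty = "n")
  invisible(x)
}

#' Extract residuals from the primary IVW fit
#'
#' Weighted residuals `(beta_out - beta_ivw * beta_exp) / se_out`; their
#' squared sum is Cochran's Q.
#'
#' @param object An `"mr_fit"`.
#' @param ... Ignored.
#' @export
residuals.mr_fit <- function(object, ...) {
  p <- object$pairs
  b <- object$estimates$beta[object$estimates$method %in% c("ivw", "wald_ratio")][1]
  (p$beta_out - b * p$beta_exp) / p$se_out
}
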