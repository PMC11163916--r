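# Closed-form two-sample MR estimators over harmonized pairs.
#
# Notation: gamma = beta_exp (variant-exposure effect), Gamma = beta_out
# (variant-outcome effect), both with standard errors. All estimators use
# first-order weights 1/se_out^2 (the conventional approximation that
# ignores uncertainty in gamma) unless noted.

new_mr_estimate <- function(method, beta, se, pval, n_snp,
                            ci_low = beta - Z95 * se,
                            ci_high = beta + Z95 * se,
                            note = NA_character_) {
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = ci_low, ci_high = ci_high, pval = pval,
         n_snp = n_snp, note = note),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  invisible(x)
}

as_pairs_df <- function(pairs) {
  df <- as.data.frame(pairs)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("pairs lack column(s): %s", paste(miss, collapse = ", "))
  if (any(df$se_out <= 0) || any(df$se_exp <= 0)) stopf("standard errors must be positive")
  df
}

#' Wald ratio estimate from a single variant
#'
#' beta = beta_out / beta_exp with the first-order standard error
#' se_out / |beta_exp|.
#'
#' @param pair A one-row harmonized pair.
#' @return An `"mr_estimate"`.
#' @export
wald_ratio <- function(pair) {
  p <- as_pairs_df(pair)
  if (nrow(p) != 1) stopf("wald_ratio takes exactly one pair")
  if (p$beta_exp == 0) stopf("degenerate instrument: beta_exp = 0")
  beta <- p$beta_out / p$beta_exp
  se <- p$se_out / abs(p$beta_exp)
  new_mr_estimate("wald_ratio", beta, se,
                  two_sided_normal_p(beta / se), n_snp = 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least-squares slope of `beta_out` on `beta_exp` through the
#' origin with weights 1/se_out², i.e. the inverse-variance meta-analysis
#' of per-variant Wald ratios. Under the default multiplicative
#' random-effects model the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q / (n - 1)))`, so heterogeneity widens but never narrows
#' the interval.
#'
#' @param pairs Harmonized pairs (>= 1 row; a single pair delegates to
#'   [wald_ratio()] with a note).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `"mr_estimate"` with attribute-free fields plus `q`, `q_df`
#'   stored in `note`-free elements `q`/`q_df` on the object.
#' @export
ivw <- function(pairs, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  p <- as_pairs_df(pairs)
  if (nrow(p) < 1) stopf("ivw needs at least one pair")
  if (nrow(p) == 1) {
    est <- wald_ratio(p)
    est$method <- "ivw"
    est$note <- "single instrument; Wald ratio"
    return(est)
  }
  w <- 1 / p$se_out^2
  beta <- sum(w * p$beta_exp * p$beta_out) / sum(w * p$beta_exp^2)
  se_fixed <- sqrt(1 / sum(p$beta_exp^2 / p$se_out^2))
  q <- sum(w * (p$beta_out - beta * p$beta_exp)^2)
  df <- nrow(p) - 1L
  se <- if (effects_model == "multiplicative_random") {
    se_fixed * max(1, sqrt(q / df))
  } else {
    se_fixed
  }
  est <- new_mr_estimate("ivw", beta, se, two_sided_normal_p(beta / se),
                         n_snp = nrow(p))
  est$q <- q
  est$q_df <- df
  est$effects_model <- effects_model
  est
}

#' MR-Egger regression
#'
#' Pairs are recoded so every `beta_exp` is positive (both effects flipped
#' otherwise), then `beta_out` is regressed on `beta_exp` with an
#' intercept, weights 1/se_out². The intercept estimates the average
#' directional pleiotropic effect; a two-sided t-test (n − 2 df) on the
#' intercept is the pleiotropy test, and the slope is the
#' pleiotropy-adjusted causal estimate under the InSIDE assumption.
#' Standard errors carry the multiplicative scaling `max(1, sigma)` with
#' `sigma` the weighted residual standard deviation.
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @return A list with elements `slope` (an `"mr_estimate"`), `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(pairs) {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 3) stopf("mr_egger needs at least 3 pairs")
  flip <- p$beta_exp < 0
  p$beta_out[flip] <- -p$beta_out[flip]
  p$beta_exp[flip] <- -p$beta_exp[flip]
  if (any(p$beta_exp == 0)) stopf("degenerate instrument: beta_exp = 0")
  w <- 1 / p$se_out^2
  x <- p$beta_exp; y <- p$beta_out
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  n <- nrow(p); df <- n - 2L
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / df
  scale <- max(1, sigma2)
  se_slope <- sqrt(sw / det * scale)
  se_int <- sqrt(swxx / det * scale)
  t_mult <- stats::qt(0.975, df)
  slope_p <- 2 * stats::pt(abs(slope / se_slope), df, lower.tail = FALSE)
  int_p <- 2 * stats::pt(abs(intercept / se_int), df, lower.tail = FALSE)
  est <- new_mr_estimate("mr_egger", slope, se_slope, slope_p, n_snp = n,
                         ci_low = slope - Z95 * se_slope,
                         ci_high = slope + Z95 * se_slope)
  list(slope = est, intercept = intercept, intercept_se = se_int,
       intercept_pval = int_p)
}

# 50% crossing of the weighted empirical distribution of ratio estimates,
# midpoint cumulative convention with linear interpolation.
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(s)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median causal estimate
#'
#' Per-variant Wald ratios are ordered and the estimate is the value at
#' which the cumulative inverse-variance weight (midpoint convention)
#' crosses 50%; it is consistent when valid instruments carry more than
#' half the total weight. The standard error comes from a seeded
#' parametric bootstrap resampling each pair's effects from
#' Normal(observed, se).
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (default 1); the caller's RNG state is
#'   untouched.
#' @return An `"mr_estimate"`.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 3) stopf("weighted_median needs at least 3 pairs")
  if (any(p$beta_exp == 0)) stopf("degenerate instrument: beta_exp = 0")
  ratios <- p$beta_out / p$beta_exp
  weights <- p$beta_exp^2 / p$se_out^2  # first-order inverse ratio variance
  beta <- weighted_median_point(ratios, weights)
  boot <- with_private_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(p), p$beta_exp, p$se_exp)
      by <- stats::rnorm(nrow(p), p$beta_out, p$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / p$se_out[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", beta, se,
                  two_sided_normal_p(beta / se), n_snp = nrow(p))
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum of w_j (ratio_j − beta_ref)² with w_j = beta_exp_j² / se_out_j²,
#' referred to a chi-square with n − 1 degrees of freedom.
#'
#' @param pairs Harmonized pairs (>= 2 rows).
#' @param beta_ref Reference causal estimate, normally the IVW slope.
#' @return List with `q`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(pairs, beta_ref) {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 2) stopf("cochran_q needs at least 2 pairs")
  w <- p$beta_exp^2 / p$se_out^2
  ratios <- p$beta_out / p$beta_exp
  q <- sum(w * (ratios - beta_ref)^2)
  df <- nrow(p) - 1L
  list(q = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out influence analysis
#'
#' Re-estimates IVW with each pair excluded in turn. A pair is flagged as
#' an outlier when its exclusion flips the sign of the causal estimate or
#' moves the p-value across the nominal 0.05 line relative to the
#' full-set IVW.
#'
#' @param pairs Harmonized pairs (>= 3 rows).
#' @param effects_model Passed to [ivw()].
#' @return List with `loo_table` (one row per excluded variant:
#'   `excluded`, `beta`, `se`, `pval`) and `loo_outlier_flag`.
#' @export
leave_one_out <- function(pairs, effects_model = "multiplicative_random") {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 3) stopf("leave_one_out needs at least 3 pairs")
  full <- ivw(p, effects_model = effects_model)
  rows <- lapply(seq_len(nrow(p)), function(j) {
    est <- ivw(p[-j, , drop = FALSE], effects_model = effects_model)
    data.frame(excluded = as.character(p$variant_id[j] %||% j),
               beta = est$beta, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  flag <- any(sign(loo$beta) != sign(full$beta)) ||
    any((loo$pval < 0.05) != (full$pval < 0.05))
  list(loo_table = loo, loo_outlier_flag = flag)
}

#' Convert a log-odds estimate to an odds ratio with 95% bounds
#'
#' @param beta Log-odds-scale estimate.
#' @param se Standard error.
#' @return List with `or`, `or_low`, `or_high`.
#' @export
#' @examples
#' to_odds_ratio(-0.3481, 0.1382)  # OR about 0.706 [0.538, 0.925]
to_odds_ratio <- function(beta, se) {
  if (any(se <= 0)) stopf("se must be positive")
  list(or = exp(beta), or_low = exp(beta - Z95 * se),
       or_high = exp(beta + Z95 * se))
}
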