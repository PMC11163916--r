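# Shared fixture builders. Everything is generated in code; no files are
# stored beyond the small reference-estimates table under extdata.

# One summary-statistic record as a one-row data.frame.
rec <- function(variant_id = "rs1", effect_allele = "A", other_allele = "G",
                beta = 0.1, se = 0.01, eaf = 0.3, pval = 1e-10,
                chrom = "1", pos = 1000000L, n = 10000) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# A sumstats data.frame from stacked rec() rows.
make_sumstats <- function(...) {
  do.call(rbind, list(...))
}

# Harmonized pairs with controllable effects.
make_pairs <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                       ids = paste0("rs", seq_along(beta_exp))) {
  data.frame(variant_id = ids, beta_exp = beta_exp,
             se_exp = rep(se_exp, length.out = length(beta_exp)),
             beta_out = beta_out,
             se_out = rep(se_out, length.out = length(beta_exp)),
             stringsAsFactors = FALSE)
}

# Random harmonized-pair instance for oracle comparisons.
random_pairs <- function(n) {
  make_pairs(
    beta_exp = stats::rnorm(n, 0, 0.2) + sign(stats::rnorm(n)) * 0.05,
    beta_out = stats::rnorm(n, 0, 0.1),
    se_exp = stats::runif(n, 0.005, 0.05),
    se_out = stats::runif(n, 0.01, 0.2)
  )
}

# Independent weighted-median oracle: invert the piecewise-linear weighted
# empirical CDF (midpoint convention) with stats::approx.
wm_oracle <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

# Extract truth-aligned (uncorrupted) pairs straight from a simulated
# study pair, bypassing harmonization; used when measuring estimators.
truth_pairs <- function(sim) {
  keep <- sim$truth$is_instrument
  data.frame(variant_id = sim$truth$variant_id[keep],
             beta_exp = sim$exposure$beta[keep],
             se_exp = sim$exposure$se[keep],
             beta_out = sim$outcome$beta[keep] *
               ifelse(sim$truth$allele_swapped[keep], -1, 1),
             se_out = sim$outcome$se[keep],
             stringsAsFactors = FALSE)
}
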