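test_that("the Wald ratio divides effects and propagates the outcome error", {
  w <- wald_ratio(make_pairs(0.1, 0.05, se_out = 0.02))
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)

  w0 <- wald_ratio(make_pairs(0.1, 0))
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)

  w2 <- wald_ratio(make_pairs(0.2, -0.05, se_out = 0.01))
  expect_equal(w2$beta, -0.25)
  expect_equal(w2$se, 0.05)
  expect_equal(c(w2$ci_low, w2$ci_high), c(-0.348, -0.152))

  expect_error(wald_ratio(make_pairs(0, 0.1)), "degenerate")
})

test_that("IVW is the inverse-variance-weighted slope through the origin", {
  # closed-form check: equal weights, slope = (0.5 + 1.0) / 2
  expect_equal(ivw(make_pairs(c(1, 1), c(0.5, 1), se_out = 1))$beta, 0.75)

  # homogeneous ratios: Q = 0, fixed and random SEs coincide
  p <- make_pairs(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), se_out = 0.05)
  fixed <- ivw(p, effects_model = "fixed")
  mre <- ivw(p)
  expect_equal(mre$beta, 0.3)
  expect_equal(mre$q, 0, tolerance = 1e-20)
  expect_equal(mre$se, fixed$se)

  # a single pair reduces to the Wald ratio
  single <- ivw(make_pairs(0.1, 0.05, se_out = 0.02))
  expect_equal(single$beta, 0.5)
  expect_equal(single$se, 0.2)

  # multiplicative random effects never deflate the fixed-effect SE
  set.seed(41)
  for (i in 1:20) {
    pr <- random_pairs(sample(3:15, 1))
    expect_gte(ivw(pr)$se, ivw(pr, effects_model = "fixed")$se)
  }
})

test_that("IVW and MR-Egger match independent weighted least-squares oracles", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_pairs(sample(5:20, 1))
    w <- 1 / p$se_out^2
    # oracle route: R's QR-based weighted regression
    o_ivw <- unname(coef(lm(beta_out ~ 0 + beta_exp, data = p, weights = w)))
    expect_equal(ivw(p)$beta, o_ivw, tolerance = 1e-10)

    recoded <- p
    flip <- recoded$beta_exp < 0
    recoded$beta_out[flip] <- -recoded$beta_out[flip]
    recoded$beta_exp[flip] <- -recoded$beta_exp[flip]
    o_egger <- coef(lm(beta_out ~ beta_exp, data = recoded, weights = w))
    e <- mr_egger(p)
    expect_equal(e$intercept, unname(o_egger[1]), tolerance = 1e-10)
    expect_equal(e$slope$beta, unname(o_egger[2]), tolerance = 1e-10)
  }

  # equal weights: IVW equals the normal-equations slope sum(xy)/sum(x^2)
  set.seed(43)
  for (i in 1:20) {
    p <- random_pairs(sample(5:20, 1))
    p$se_out <- 0.1
    expect_equal(ivw(p)$beta,
                 sum(p$beta_exp * p$beta_out) / sum(p$beta_exp^2),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact linear data and refuses 2 pairs", {
  g <- c(0.1, 0.2, 0.3, 0.5)
  p <- make_pairs(g, 0.03 + 0.4 * g, se_out = 0.05)
  e <- mr_egger(p)
  expect_equal(e$slope$beta, 0.4, tolerance = 1e-12)
  expect_equal(e$intercept, 0.03, tolerance = 1e-12)

  # data exactly through the origin: intercept 0, slope equals IVW
  p0 <- make_pairs(g, 0.4 * g, se_out = 0.05)
  e0 <- mr_egger(p0)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  expect_equal(e0$slope$beta, ivw(p0)$beta, tolerance = 1e-10)

  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1))), "3 pairs")
})

test_that("the weighted median interpolates the 50% crossing of the cumulative weights", {
  # middle mass point of three equal weights
  p <- make_pairs(c(1, 1, 1), c(0.1, 0.5, 0.9), se_out = 1)
  expect_equal(weighted_median(p, n_boot = 20)$beta, 0.5)

  # all ratios equal: the bootstrap SE approximates the analytic ratio SE
  pe <- make_pairs(rep(0.2, 5), rep(0.06, 5), se_exp = 1e-6, se_out = 0.02)
  wm <- weighted_median(pe, n_boot = 500, seed = 7)
  expect_equal(wm$beta, 0.3)
  # same order as the analytic common-ratio SE (median-vs-mean efficiency
  # makes it slightly larger at n = 5)
  analytic <- 0.02 / 0.2 / sqrt(5)
  expect_equal(wm$se, analytic, tolerance = 0.3)

  # asymmetric weights: crossing interpolates between ratios 1 and 2
  pw <- make_pairs(rep(1, 4), c(0, 1, 2, 3),
                   se_out = 1 / sqrt(c(0.4, 0.1, 0.1, 0.4)))
  expect_equal(weighted_median(pw, n_boot = 20)$beta, 1.5)

  # exhaustive crossing oracle on random instances
  set.seed(44)
  for (i in 1:50) {
    p <- random_pairs(sample(3:20, 1))
    got <- weighted_median(p, n_boot = 2)$beta
    want <- wm_oracle(p$beta_out / p$beta_exp, p$beta_exp^2 / p$se_out^2)
    expect_equal(got, want, tolerance = 1e-12)
  }

  expect_error(weighted_median(make_pairs(1, 1)), "3 pairs")
})

test_that("the weighted-median bootstrap is seeded and leaves the caller's RNG alone", {
  p <- random_pairs(6)
  a <- weighted_median(p, n_boot = 100, seed = 5)
  b <- weighted_median(p, n_boot = 100, seed = 5)
  expect_identical(a$se, b$se)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(weighted_median(p, n_boot = 10, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("Cochran's Q measures ratio heterogeneity around the reference", {
  # homogeneous ratios
  p <- make_pairs(c(0.1, 0.2), c(0.05, 0.10), se_out = 0.03)
  q <- cochran_q(p, 0.5)
  expect_equal(q$q, 0, tolerance = 1e-25)
  expect_equal(q$q_pval, 1)

  # hand computation: ratios 0 and 1, unit weights, reference 0.5
  p2 <- make_pairs(c(1, 1), c(0, 1), se_out = 1)
  q2 <- cochran_q(p2, 0.5)
  expect_equal(q2$q, 0.5)
  expect_equal(q2$q_df, 1)

  # invariant to relabeling
  set.seed(45)
  p3 <- random_pairs(8)
  expect_equal(cochran_q(p3, 0.2)$q, cochran_q(p3[sample(8), ], 0.2)$q)
})

test_that("leave-one-out flags a variant whose removal flips the estimate", {
  # five homogeneous pairs: every exclusion reproduces the full estimate
  p <- make_pairs(rep(0.2, 5), rep(0.06, 5), se_out = 0.02)
  loo <- leave_one_out(p)
  expect_equal(nrow(loo$loo_table), 5)
  expect_true(all(abs(loo$loo_table$beta - 0.3) < 1e-12))
  expect_false(loo$loo_outlier_flag)

  # one dominant outlier drives the slope; its removal flips the sign
  pout <- make_pairs(c(0.1, 0.1, 0.1, 1.0),
                     c(-0.001, -0.002, -0.0015, 0.5),
                     se_out = c(0.05, 0.05, 0.05, 0.01))
  full <- ivw(pout)
  loo2 <- leave_one_out(pout)
  expect_true(loo2$loo_outlier_flag)
  expect_true(any(sign(loo2$loo_table$beta) != sign(full$beta)))
})

test_that("odds-ratio conversion is multiplicatively symmetric and matches a reported row", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$or_high * o$or_low, 1, tolerance = 1e-12)

  # log-odds -0.3481 (se 0.1382): OR 0.706, 95% CI [0.538, 0.925]
  o2 <- to_odds_ratio(-0.3481, 0.1382)
  expect_equal(o2$or, 0.706, tolerance = 5e-4)
  expect_equal(o2$or_low, 0.538, tolerance = 1e-3)
  expect_equal(o2$or_high, 0.925, tolerance = 1e-3)

  set.seed(46)
  b <- rnorm(10); s <- runif(10, 0.01, 1)
  o3 <- to_odds_ratio(b, s)
  expect_equal(o3$or_high / o3$or, o3$or / o3$or_low, tolerance = 1e-12)
})

test_that("all estimators are equivariant under negating the outcome", {
  set.seed(47)
  p <- random_pairs(10)
  neg <- p; neg$beta_out <- -neg$beta_out
  f1 <- mr_fit(p, n_boot = 50, seed = 3)
  f2 <- mr_fit(neg, n_boot = 50, seed = 3)
  expect_equal(f2$estimates$beta, -f1$estimates$beta, tolerance = 1e-12)
  analytic <- f1$estimates$method != "weighted_median"
  expect_equal(f2$estimates$se[analytic], f1$estimates$se[analytic],
               tolerance = 1e-12)
  # the weighted-median SE is a bootstrap quantity: invariant in
  # distribution, equal only up to Monte-Carlo error
  expect_equal(f2$estimates$se[!analytic], f1$estimates$se[!analytic],
               tolerance = 0.5)
  expect_equal(f2$sensitivity$q, f1$sensitivity$q, tolerance = 1e-12)
})

test_that("the fitted model object exposes estimates through the standard generics", {
  set.seed(48)
  p <- random_pairs(8)
  fit <- mr_fit(p, outcome_type = "binary", n_boot = 50)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), c("ivw", "mr_egger", "weighted_median"))
  ci <- confint(fit)
  expect_equal(unname(ci[, 1]), fit$estimates$ci_low)
  expect_equal(fit$estimates$or, exp(fit$estimates$beta))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$beta &
                    fit$estimates$beta <= fit$estimates$ci_high))
  # weighted residuals square-sum to Cochran's Q
  expect_equal(sum(residuals(fit)^2), fit$sensitivity$q, tolerance = 1e-12)
  expect_output(print(summary(fit)), "Egger intercept")
  # single-instrument fit degrades to the Wald ratio
  f1 <- mr_fit(p[1, ])
  expect_equal(f1$estimates$method, "wald_ratio")
  # Q/df > 1 reproduces the multiplicative SE inflation exactly
  if (fit$sensitivity$q / fit$sensitivity$q_df > 1) {
    fixed <- ivw(p, effects_model = "fixed")
    expect_equal(fit$estimates$se[1],
                 fixed$se * sqrt(fit$sensitivity$q / fit$sensitivity$q_df),
                 tolerance = 1e-12)
  }
})
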