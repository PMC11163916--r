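test_that("p-value selection falls back to the relaxed threshold when too few variants pass", {
  df <- make_sumstats(rec("rs1", pval = 1e-9), rec("rs2", pval = 1e-7),
                      rec("rs3", pval = 1e-5))
  sel <- select_by_pvalue(df, min_count = 3)
  expect_equal(sort(sel$variant_id), c("rs1", "rs2"))
  expect_equal(attr(sel, "threshold_used"), 5e-6)

  # enough at the primary threshold: no fallback
  df2 <- make_sumstats(rec("rs1", pval = 1e-9), rec("rs2", pval = 1e-9),
                       rec("rs3", pval = 1e-9))
  sel2 <- select_by_pvalue(df2, min_count = 3)
  expect_equal(nrow(sel2), 3)
  expect_equal(attr(sel2, "threshold_used"), 5e-8)

  # nothing passes either threshold: empty with a warning
  expect_warning(sel3 <- select_by_pvalue(make_sumstats(rec("rs1", pval = 0.01))),
                 "no variants pass")
  expect_equal(nrow(sel3), 0)
})

test_that("greedy clumping keeps the strongest variant per LD window", {
  # different chromosomes: the window test fails first, both kept
  a <- rec("rs1", chrom = "1", pos = 1e6, pval = 1e-10)
  b <- rec("rs2", chrom = "2", pos = 1e6, pval = 1e-8)
  ld <- ld_matrix(matrix(c(1, 0.9, 0.9, 1), 2,
                         dimnames = list(c("rs1", "rs2"), c("rs1", "rs2"))))
  expect_equal(nrow(clump(make_sumstats(a, b), ld)), 2)

  # same chromosome, 5,000 kb apart, r2 = 0.5: weaker variant removed
  b$chrom <- "1"; b$pos <- 1e6 + 5e6
  ld05 <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2,
                           dimnames = list(c("rs1", "rs2"), c("rs1", "rs2"))))
  out <- clump(make_sumstats(a, b), ld05)
  expect_equal(out$variant_id, "rs1")
  expect_equal(attr(out, "clump_log")$variant_id, "rs2")

  # r2 below the threshold: both kept
  ld_lo <- ld_matrix(matrix(c(1, 5e-4, 5e-4, 1), 2,
                            dimnames = list(c("rs1", "rs2"), c("rs1", "rs2"))))
  expect_equal(nrow(clump(make_sumstats(a, b), ld_lo)), 2)

  # missing positions are an error naming the variant
  c_na <- rec("rs3", pos = NA)
  expect_error(clump(make_sumstats(a, c_na), ld), "rs3")
})

test_that("clumped sets are pairwise independent and deterministic under p-value ties", {
  set.seed(21)
  for (iter in 1:5) {
    n <- 12
    ids <- sprintf("rs%02d", 1:n)
    df <- do.call(rbind, lapply(1:n, function(i) {
      rec(ids[i], chrom = as.character(1 + (i %% 2)),
          pos = 1e6 + (i %/% 2) * 2e6,
          pval = sample(c(1e-9, 1e-8, 1e-8), 1))
    }))
    m <- matrix(runif(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    ld <- ld_matrix(m)
    out1 <- clump(df, ld, window_kb = 10000, r2_max = 0.1)
    out2 <- clump(df[sample(n), ], ld, window_kb = 10000, r2_max = 0.1)
    # deterministic regardless of input row order (ties broken by id)
    expect_equal(sort(out1$variant_id), sort(out2$variant_id))
    # exhaustive pairwise independence check
    if (nrow(out1) > 1) {
      for (i in 1:(nrow(out1) - 1)) for (j in (i + 1):nrow(out1)) {
        same_chr <- out1$chrom[i] == out1$chrom[j]
        close <- abs(out1$pos[i] - out1$pos[j]) <= 1e7
        if (same_chr && close) {
          expect_lt(ld[out1$variant_id[i], out1$variant_id[j]], 0.1)
        }
      }
    }
  }
})

test_that("variance explained follows 2*MAF*(1-MAF)*beta^2 with MAF symmetry", {
  expect_equal(variance_explained(0.5, 1), 0.5)
  expect_equal(variance_explained(0.9, 0.2), 0.0072)
  expect_equal(variance_explained(0.3, 0), 0)
  # invariant under eaf -> 1 - eaf and beta -> -beta
  set.seed(5)
  eaf <- runif(20, 0.01, 0.99); beta <- rnorm(20, 0, 0.3)
  expect_equal(variance_explained(eaf, beta), variance_explained(1 - eaf, beta))
  expect_equal(variance_explained(eaf, beta), variance_explained(eaf, -beta))
  expect_error(variance_explained(1.0, 0.2), "eaf")
  expect_warning(capped <- variance_explained(0.5, 2), "capping")
  expect_lt(capped, 1)
})

test_that("the F-statistic follows R2/(1-R2) * (n-k-1)/k and grows with R2", {
  expect_equal(f_statistic(0.5, 1002, 1), 1000)
  expect_equal(f_statistic(0.0072, 14824, 1), 0.0072 / 0.9928 * 14822,
               tolerance = 1e-12)
  expect_equal(round(f_statistic(0.0072, 14824, 1), 2), 107.49)
  expect_equal(f_statistic(0, 100, 1), 0)
  grid <- seq(0.001, 0.9, length.out = 50)
  expect_true(all(diff(f_statistic(grid, 5000, 3)) > 0))
  expect_error(f_statistic(0.1, 2, 1), "n > k")
})

test_that("weak instruments are excluded at F < 10 with the boundary retained", {
  df <- make_sumstats(rec("rs1", eaf = 0.5, beta = 1, n = 41),   # F = 39/(1) * r2/(1-r2); engineered below
                      rec("rs2"), rec("rs3"))
  # engineer exact per-variant F values through a hand-built set
  iset <- instrument_set(make_sumstats(rec("rs1"), rec("rs2"), rec("rs3")),
                         "exp")
  iset$records$f_stat <- c(9.9, 10.0, 500)
  kept <- filter_weak(iset, f_min = 10)
  expect_equal(kept$records$variant_id, c("rs2", "rs3"))
  expect_equal(kept$selection_log$variant_id, "rs1")

  all_strong <- instrument_set(make_sumstats(rec("rs1"), rec("rs2")), "exp")
  all_strong$records$f_stat <- c(50, 60)
  expect_equal(nrow(filter_weak(all_strong)$records), 2)

  none <- instrument_set(make_sumstats(rec("rs1")), "exp")
  none$records$f_stat <- 1
  expect_warning(out <- filter_weak(none), "all instruments weak")
  expect_equal(nrow(out$records), 0)
})

test_that("instrument sets report per-variant and aggregate strength", {
  df <- make_sumstats(rec("rs1", eaf = 0.9, beta = 0.2, n = 14824),
                      rec("rs2", eaf = 0.5, beta = 0.1, n = 14824))
  iset <- instrument_set(df, "cytokine")
  expect_equal(iset$records$r2_explained[1], 0.0072)
  expect_equal(iset$records$f_stat[1], f_statistic(0.0072, 14824, 1))
  r2_sum <- sum(iset$records$r2_explained)
  expect_equal(iset$aggregate_f, f_statistic(r2_sum, 14824, 2))
})

test_that("LD matrices round-trip through square and long file formats", {
  ids <- c("rs1", "rs2", "rs3")
  m <- diag(1, 3); m[1, 2] <- m[2, 1] <- 0.4
  dimnames(m) <- list(ids, ids)
  ld <- ld_matrix(m)
  sq <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, sq)
  expect_equal(unclass(read_ld_matrix(sq)), unclass(ld), ignore_attr = TRUE)

  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id1\tid2\tr2", "rs1\trs2\t0.4", "rs1\trs3\t0",
               "rs2\trs3\t0"), long)
  expect_equal(read_ld_matrix(long)["rs1", "rs2"], 0.4)

  bad <- m; bad[1, 1] <- 0.5
  expect_error(ld_matrix(bad), "diagonal")
})
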