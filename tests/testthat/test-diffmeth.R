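test_that("group levels are read-weighted means of pooled counts", {
  sheet <- mk_wild_sheet(c("A", "B"), c(2, 2))
  M <- mk_matrix(list(
    list(chrom = "chr1", pos = 10, cov = c(10, 10, 10, 10), meth = c(5, 5, 8, 8)),
    list(chrom = "chr1", pos = 20, cov = c(10, 10, 10, 10), meth = c(3, 3, 3, 3)),
    list(chrom = "chr1", pos = 30, cov = c(10, 10, 10, 10), meth = c(1, 9, 2, 2)),
    list(chrom = "chr1", pos = 40, cov = c(NA, NA, 10, 10), meth = c(NA, NA, 5, 5))
  ), sheet$sample)
  lv <- group_levels(M, sheet, "A", "B")
  expect_equal(lv$level_a[1], 50)
  expect_equal(lv$level_b[1], 80)
  expect_equal(lv$meth_diff[1], 30)
  expect_equal(lv$meth_diff[2], 0)
  ## weighted equals unweighted only at equal coverage: here (1+9)/(10+10)
  expect_equal(lv$level_a[3], 100 * (1 + 9) / 20)
  ## absent group -> absent result
  expect_true(is.na(lv$level_a[4]) && is.na(lv$meth_diff[4]))
  ## independent weighted-mean oracle on uneven coverages
  M2 <- mk_matrix(list(list(chrom = "chr1", pos = 5,
                            cov = c(40, 5, 10, 10), meth = c(20, 5, 1, 1))),
                  sheet$sample)
  lv2 <- group_levels(M2, sheet, "A", "B")
  expect_equal(lv2$level_a, 100 * (20 + 5) / (40 + 5))
})

test_that("the no-covariate LRT equals the pooled G-statistic", {
  ## reference fixture: 10 vs 10 samples of 10 reads, pooled (90,10) vs (10,90)
  ma <- rep(9L, 10); mb <- rep(1L, 10); cv <- rep(10L, 10)
  g <- g_stat_pooled(ma, cv, mb, cv)
  r <- site_lrt(c(ma, mb), c(cv, cv), rep(c("a", "b"), each = 10))
  expect_equal(g, 147.2257, tolerance = 1e-5)
  expect_lt(abs(r$lrt_stat - g), 1e-6)
  expect_equal(r$df, 1L)

  ## identical pooled proportions: statistic 0, p 1
  r0 <- site_lrt(c(5L, 5L, 5L, 5L), rep(10L, 4), rep(c("a", "b"), each = 2))
  expect_lt(r0$lrt_stat, 1e-10)
  expect_equal(r0$p, 1, tolerance = 1e-8)

  ## randomized agreement across many small instances
  withr::with_seed(42, {
    for (i in 1:50) {
      na <- sample(2:8, 1); nb <- sample(2:8, 1)
      cva <- sample(1:40, na, replace = TRUE)
      cvb <- sample(1:40, nb, replace = TRUE)
      mta <- rbinom(na, cva, runif(1, 0.05, 0.95))
      mtb <- rbinom(nb, cvb, runif(1, 0.05, 0.95))
      r <- site_lrt(c(mta, mtb), c(cva, cvb), rep(c("a", "b"), c(na, nb)))
      expect_lt(abs(r$lrt_stat - g_stat_pooled(mta, cva, mtb, cvb)), 1e-6)
    }
  })
})

test_that("a family covariate confounded with group is flagged", {
  r <- site_lrt(c(5L, 6L, 1L, 2L), rep(10L, 4), rep(c("a", "b"), each = 2),
                family = c("f1", "f1", "f2", "f2"))
  expect_equal(r$flag, "rank_deficient")
  expect_true(is.na(r$p))
  ## balanced family across groups is fine
  r2 <- site_lrt(c(5L, 6L, 1L, 2L), rep(10L, 4), rep(c("a", "b"), each = 2),
                 family = c("f1", "f2", "f1", "f2"))
  expect_equal(r2$flag, "")
  expect_false(is.na(r2$p))
})

test_that("BH adjustment follows the step-up definition and handles edges", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(numeric(0)), numeric(0))
  ## permutation invariance and q >= p
  withr::with_seed(1, {
    p <- runif(50)
    perm <- sample(50)
    expect_equal(adjust_pvalues(p)[perm], adjust_pvalues(p[perm]))
    expect_true(all(adjust_pvalues(p) >= p))
  })
})

test_that("DMS calling applies strict q and inclusive effect-size thresholds", {
  res <- data.frame(q = c(0.01, 0.0125, 0.001, 0.001),
                    meth_diff = c(20, 20, 14.9, 15))
  expect_equal(call_dms(res, 0.0125, 15), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("compare_groups attaches the family covariate only for experimental pairs", {
  withr::with_seed(7, {
    groups <- c("ctrlX", "treatX")
    rows <- do.call(rbind, lapply(groups, function(g) {
      data.frame(sample = sprintf("%s_%d", g, 1:6), cohort = "experimental",
                 group = g, family = paste0("f", rep(1:3, 2)), sex = "unknown",
                 stringsAsFactors = FALSE)
    }))
    sheet <- sample_sheet(rows)
    cov <- matrix(30L, 20, 12)
    met <- matrix(rbinom(240, 30, 0.5), 20, 12)
    M <- meth_matrix(rep("chr1", 20), seq_len(20) * 10L, sheet$sample, cov, met)
    tab <- compare_groups(M, sheet, "ctrlX", "treatX")
    expect_equal(attr(tab, "covariate"), "family")

    wild <- mk_wild_sheet(c("ctrlX", "treatX"), c(6, 6))
    wild$sample <- sheet$sample
    tab2 <- compare_groups(M, wild, "ctrlX", "treatX")
    expect_equal(attr(tab2, "covariate"), "none")
  })
})

test_that("a split-half null comparison calls no DMS", {
  withr::with_seed(11, {
    sheet <- mk_wild_sheet(c("halfA", "halfB"), c(8, 8))
    cov <- matrix(rnbinom(300 * 16, mu = 30, size = 5) + 1L, 300, 16)
    pi0 <- runif(300, 0.1, 0.9)
    met <- matrix(rbinom(300 * 16, as.vector(cov), rep(pi0, 16)), 300, 16)
    M <- meth_matrix(rep("chr1", 300), seq_len(300) * 10L, sheet$sample, cov, met)
    tab <- compare_groups(M, sheet, "halfA", "halfB")
    expect_equal(sum(tab$dms), 0L)
  })
})
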