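test_that("minimum-coverage filter is boundary-inclusive and drops empty sites", {
  M <- mk_matrix(list(
    list(chrom = "chr1", pos = 10, cov = c(9, 30), meth = c(4, 10)),
    list(chrom = "chr1", pos = 20, cov = c(10, 10), meth = c(5, 5)),
    list(chrom = "chr1", pos = 30, cov = c(9, 9), meth = c(1, 1))
  ), c("s1", "s2"))
  out <- suppressMessages(filter_min_coverage(M, 10))
  expect_equal(out$sites$pos, c(10L, 20L))       # all-absent site dropped
  expect_true(is.na(out$coverage[1, "s1"]))      # coverage 9 -> absent
  expect_equal(unname(out$coverage[2, "s1"]), 10L)       # coverage 10 retained
})

test_that("high-coverage cap uses the linear-interpolation percentile per sample", {
  cov <- matrix(c(1:1000, rep(10L, 1000)), ncol = 2)
  met <- matrix(0L, 1000, 2)
  M <- meth_matrix(rep("chr1", 1000), seq_len(1000), c("s1", "s2"), cov, met)
  out <- suppressMessages(filter_high_coverage(M, 99.9))
  ## sample 1: threshold quantile(1:1000, .999) = 999.001 -> only 1000 removed
  expect_equal(sum(is.na(out$coverage[, "s1"])), 1L)
  expect_true(is.na(out$coverage[out$sites$pos == 1000, "s1"]))
  expect_equal(sum(is.na(out$coverage[, "s2"])), 0L)  # uniform -> untouched
  ## percentile 100 removes nothing
  out100 <- suppressMessages(filter_high_coverage(M, 100))
  expect_same_matrix(out100, M)
  ## independent check against stats::quantile on a random matrix
  R <- random_matrix(seed = 3)
  outR <- suppressMessages(suppressWarnings(filter_high_coverage(R, 90)))
  keyR <- paste(R$sites$chrom, R$sites$pos)
  keyO <- paste(outR$sites$chrom, outR$sites$pos)
  for (j in seq_along(R$samples)) {
    x <- R$coverage[, j]
    thr <- quantile(x[!is.na(x)], 0.9, names = FALSE)
    kept <- keyR[!is.na(x) & x <= thr]            # entries expected to survive
    surv <- keyO[!is.na(outR$coverage[, j])]
    expect_setequal(surv, kept)
  }
})

test_that("SNP correction removes C>T and G>A overlaps passing MAF and GQ", {
  M <- mk_matrix(list(
    list(chrom = "chr1", pos = 100, cov = c(20, 20), meth = c(5, 5)),
    list(chrom = "chr1", pos = 200, cov = c(20, 20), meth = c(5, 5)),
    list(chrom = "chr1", pos = 300, cov = c(20, 20), meth = c(5, 5)),
    list(chrom = "chr1", pos = 400, cov = c(20, 20), meth = c(5, 5))
  ), c("s1", "s2"))
  gt <- matrix(c("0/1", "0/1",   # C>T at CpG C (pos 100): remove
                 "0/1", "1/1",   # G>A at pos+1 of CpG 200 (201): remove
                 "0/1", "0/0",   # A>G at pos 300: keep
                 "0/1", "0/1"),  # C>T at 400 but low GQ: keep
               4, 2, byrow = TRUE, dimnames = list(NULL, c("s1", "s2")))
  V <- variant_table(rep("chr1", 4), c(100L, 201L, 300L, 400L),
                     c("C", "G", "A", "C"), c("T", "A", "G", "T"),
                     gt, dp = matrix(20, 4, 2),
                     gq = matrix(c(40, 40, 40, 40, 40, 40, 10, 10),
                                 4, 2, byrow = TRUE))
  out <- suppressMessages(correct_snp_overlap(M, V, min_gq = 20, min_maf = 0.005))
  expect_equal(out$sites$pos, c(300L, 400L))
})

test_that("coverage normalization matches the stated scaling rule", {
  ## two samples with medians 10 and 20: target median-of-medians 15,
  ## factors 1.5 and 0.75
  M <- mk_matrix(list(
    list(chrom = "chr1", pos = 10, cov = c(10, 20), meth = c(5, 10)),
    list(chrom = "chr1", pos = 20, cov = c(10, 20), meth = c(0, 20)),
    list(chrom = "chr1", pos = 30, cov = c(10, 20), meth = c(10, 0))
  ), c("s1", "s2"))
  out <- normalize_coverage(M)
  expect_equal(unname(out$coverage[1, ]), c(15L, 15L))
  expect_equal(unname(out$methylated[1, ]), c(8L, 8L))  # fraction kept to rounding
  ## equal medians: identity
  eq <- normalize_coverage(random_matrix(seed = 5))
  expect_same_matrix(normalize_coverage(eq), eq)
  ## methylation fraction moves by at most 1/coverage'
  R <- random_matrix(seed = 7)
  N <- normalize_coverage(R)
  pres <- !is.na(R$coverage)
  d <- abs(N$methylated[pres] / N$coverage[pres] -
             R$methylated[pres] / R$coverage[pres])
  expect_true(all(d <= 1 / N$coverage[pres] + 1e-12))
})

test_that("presence filter enforces the per-group minimum in every group", {
  sheet <- mk_wild_sheet(c("A", "B"), c(3, 3))
  M <- mk_matrix(list(
    list(chrom = "chr1", pos = 10, cov = c(10, 10, 10, 10, 10, 10), meth = rep(1, 6)),
    list(chrom = "chr1", pos = 20, cov = c(10, 10, NA, 10, 10, 10), meth = c(1, 1, NA, 1, 1, 1)),
    list(chrom = "chr1", pos = 30, cov = c(10, NA, NA, 10, 10, 10), meth = c(1, NA, NA, 1, 1, 1))
  ), sheet$sample)
  out <- suppressMessages(filter_presence(M, sheet, c("A", "B"), 3))
  expect_equal(out$sites$pos, 10L)
  out2 <- suppressMessages(filter_presence(M, sheet, c("A", "B"), 2))
  expect_equal(out2$sites$pos, c(10L, 20L))
  expect_equal(n_sites(suppressMessages(filter_presence(M, sheet, c("A", "B"), 0))), 3L)
  expect_error(filter_presence(M, sheet, c("A", "B"), 4), "unsatisfiable")
})

test_that("chromosome drop removes all its sites and commutes with presence", {
  sheet <- mk_wild_sheet(c("A", "B"), c(4, 4))
  M <- random_matrix(n_samples = 8, seed = 13)
  colnames(M$coverage) <- colnames(M$methylated) <- sheet$sample
  M$samples <- sheet$sample
  a <- suppressMessages(filter_presence(drop_chromosome(M, "chr2"), sheet, c("A", "B"), 2))
  b <- suppressMessages(drop_chromosome(filter_presence(M, sheet, c("A", "B"), 2), "chr2"))
  expect_same_matrix(a, b)
  expect_false("chr2" %in% a$sites$chrom)
  expect_warning(drop_chromosome(M, "chrZ"), "no-op")
})

test_that("blacklist subtraction is a plain set difference on (chrom, pos)", {
  dms <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L))
  blk <- data.frame(chrom = "chr1", pos = c(2L, 9L))
  expect_equal(suppressMessages(drop_blacklist(dms, blk))$pos, c(1L, 3L))
  expect_equal(drop_blacklist(dms, blk[0, ]), dms)
  expect_equal(nrow(suppressMessages(drop_blacklist(dms, dms))), 0L)
})
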