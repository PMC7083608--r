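test_that("genome layouts are collision-free, sorted and reproducible", {
  la <- generate_layout(n_cpg = 600, n_genes = 20, chrom_len = 3e5, seed = 9)
  lb <- generate_layout(n_cpg = 600, n_genes = 20, chrom_len = 3e5, seed = 9)
  expect_identical(la, lb)
  expect_equal(nrow(la$cpgs), 600L)
  expect_false(anyDuplicated(paste(la$cpgs$chrom, la$cpgs$pos)) > 0)
  ## positions even: a CpG's G (pos+1) never collides with the next C
  expect_true(all(la$cpgs$pos %% 2 == 0))
  expect_true(any(la$chroms$is_sex))
  ## genes non-overlapping within chromosomes, exons inside genes
  for (ch in unique(la$genes$genes$chrom)) {
    g <- la$genes$genes[la$genes$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  ## no genes at all: everything intergenic
  l0 <- generate_layout(n_cpg = 100, n_genes = 0, chrom_len = 3e5, seed = 9)
  f <- annotate_features(l0$cpgs, l0$genes)
  expect_true(all(f$feature == "intergenic"))
})

test_that("a null scenario reproduces its baselines within binomial noise", {
  layout <- generate_layout(n_cpg = 400, n_genes = 0, chrom_len = 3e5, seed = 2)
  params <- sim_params(n_inducible_expected = 0, n_inducible_opposite = 0,
                       n_inconclusive = 0, n_stable_only = 0,
                       rho = 0, sigma_family = 0)
  sim <- simulate_methylation(layout, two_pop_design(), params, seed = 3)
  pooled <- rowSums(sim$matrix$methylated) / rowSums(sim$matrix$coverage)
  ## truth rows are in layout order; align on (chrom, pos)
  i <- match(paste(sim$matrix$sites$chrom, sim$matrix$sites$pos),
             paste(sim$truth$chrom, sim$truth$pos))
  mu <- pmin(pmax(sim$truth$pi0[i], 0.01), 0.99)
  dev <- abs(pooled - mu)
  ## pooled over ~ 31 x 30 reads: binomial sd <= 0.017
  expect_lt(mean(dev), 0.02)
  expect_lt(max(dev), 0.1)
})

test_that("planted population effects are realized at their nominal size", {
  layout <- generate_layout(n_cpg = 1000, n_genes = 0, seed = 4)
  sim <- suppressMessages(
    simulate_methylation(layout, two_pop_design(), sim_params(sigma_family = 0),
                         seed = 5))
  lv <- group_levels(sim$matrix, sim$sheet, "KIE20", "NYN6")
  planted <- sim$truth$class != "null"
  expect_equal(sum(planted), 100L)
  key_t <- paste(sim$truth$chrom, sim$truth$pos)
  key_l <- paste(lv$chrom, lv$pos)
  i <- match(key_t[planted], key_l)
  realized <- lv$meth_diff[i] * sign(sim$truth$delta_wild[planted])
  expect_gt(mean(realized), 27)
  expect_lt(mean(realized), 33)
})

test_that("generators are pure functions of their seed", {
  layout <- generate_layout(n_cpg = 200, n_genes = 5, chrom_len = 3e5, seed = 7)
  s1 <- suppressMessages(simulate_methylation(layout, seed = 8))
  s2 <- suppressMessages(simulate_methylation(layout, seed = 8))
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  g1 <- simulate_genotypes(layout, s1$sheet, s1$truth, n_snps = 300, seed = 9)
  g2 <- simulate_genotypes(layout, s1$sheet, s1$truth, n_snps = 300, seed = 9)
  expect_identical(g1$gt, g2$gt)
  ## on-disk VCF identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_vcf_minimal(g1, f1); write_vcf_minimal(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted inducible sites receive guaranteed window SNPs", {
  layout <- generate_layout(n_cpg = 400, n_genes = 0, seed = 10)
  sim <- suppressMessages(simulate_methylation(layout, seed = 11))
  V <- simulate_genotypes(layout, sim$sheet, sim$truth, n_snps = 500, seed = 12)
  ind <- sim$truth[sim$truth$class %in% c("inducible-expected",
                                          "inducible-opposite"), ]
  for (i in seq_len(min(nrow(ind), 10))) {
    n_near <- sum(V$chrom == ind$chrom[i] & abs(V$pos - ind$pos[i]) <= 5000)
    expect_gte(n_near, 10)
  }
  st <- attr(V, "snp_truth")
  expect_true(all(c("background", "inducible-expected",
                    "inducible-opposite") %in% st$class))
})

test_that("injected CpG SNPs respect the configured fraction and thresholds", {
  layout <- generate_layout(n_cpg = 400, n_genes = 0, seed = 13)
  sim <- suppressMessages(simulate_methylation(layout, seed = 14))
  V <- simulate_genotypes(layout, sim$sheet, sim$truth, n_snps = 200, seed = 15)
  V0 <- inject_cpg_snps(V, layout, fraction = 0, seed = 16)
  expect_equal(length(V0$pos), length(V$pos))      # fraction 0: identity
  Vi <- inject_cpg_snps(V, layout, fraction = 0.1, maf = 0.05, seed = 16)
  inj <- attr(Vi, "injected")
  expect_equal(nrow(inj), 40L)
  expect_true(all(inj$type %in% c("C>T", "G>A")))
  ## a high MAF threshold leaves every injected site untouched
  M <- sim$matrix
  out <- suppressMessages(correct_snp_overlap(M, Vi, min_gq = 20, min_maf = 0.5))
  expect_equal(n_sites(out), n_sites(M))
})
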