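mk_genes <- function() {
  gene_models(
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = c("chr1", "chr1", "chr1"),
               strand = c("+", "-", "+"),
               start = c(10000L, 30000L, 9200L),
               end = c(15000L, 36000L, 9600L),
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("gA", "gA", "gB", "gC"), chrom = "chr1",
               start = c(10000L, 13000L, 30000L, 9200L),
               end = c(10500L, 15000L, 36000L, 9600L),
               stringsAsFactors = FALSE)
  )
}

test_that("feature calls respect the promoter definition and precedence", {
  genes <- mk_genes()
  ## 1500 bp upstream of the + strand TSS at 10000: promoter
  f <- annotate_feature("chr1", 9000L, genes)
  expect_equal(f$feature, "promoter")
  ## inside an exon of gC (9200-9600) but also in gA's promoter window:
  ## promoter wins across genes
  f2 <- annotate_feature("chr1", 9300L, genes)
  expect_equal(f2$feature, "promoter")
  ## within gA but between exons: intron
  f3 <- annotate_feature("chr1", 11000L, genes)
  expect_equal(f3$feature, "intron")
  ## - strand promoter extends 1500 bp beyond the gene end (TSS 36000)
  f4 <- annotate_feature("chr1", 37000L, genes)
  expect_equal(f4$feature, "promoter")
  ## far from everything: intergenic
  f5 <- annotate_feature("chr1", 60000L, genes)
  expect_equal(f5$feature, "intergenic")
})

test_that("gene association uses gene spans and the 10-kb TSS rule inclusively", {
  genes <- mk_genes()
  sites <- data.frame(chrom = "chr1", pos = c(11000L, 19999L, 20001L, 80000L))
  calls <- associate_gene(annotate_features(sites, genes), tss_assoc_bp = 10000)
  expect_equal(calls$gene_id[1], "gA")          # intronic -> its gene
  expect_equal(calls$gene_id[2], "gA")          # 9999 bp from TSS: associated
  ## 20001 is 10001 bp from gA's TSS but 9999 bp inside gB's window? check:
  ## |20001 - 36000| = 15999 -> unassociated
  expect_true(is.na(calls$gene_id[3]))
  expect_true(is.na(calls$gene_id[4]))
  ## signed distance: negative upstream of the TSS in gene orientation
  expect_equal(calls$tss_dist[2], 19999 - 10000)
  up <- associate_gene(annotate_features(
    data.frame(chrom = "chr1", pos = 9000L), genes))
  expect_lt(up$tss_dist, 0)
})

test_that("feature calls are invariant to gene input order", {
  genes <- mk_genes()
  rev_genes <- gene_models(genes$genes[3:1, c("gene_id", "chrom", "strand",
                                              "start", "end")],
                           genes$exons[nrow(genes$exons):1, ])
  sites <- data.frame(chrom = "chr1",
                      pos = c(9000L, 9300L, 11000L, 23000L, 37000L, 60000L))
  a <- annotate_features(sites, genes)
  b <- annotate_features(sites, rev_genes)
  expect_equal(a, b)
})

test_that("the feature distribution test matches the direct chi-square formula", {
  ## identical proportions: exactly zero
  r0 <- feature_distribution_test(c(promoter = 10, exon = 10, intron = 10,
                                    intergenic = 10),
                                  c(promoter = 25, exon = 25, intron = 25,
                                    intergenic = 25))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  ## hand-computed fixture, cross-checked against stats::chisq.test
  obs <- c(promoter = 12, exon = 30, intron = 25, intergenic = 33)
  bg <- c(promoter = 200, exon = 300, intron = 250, intergenic = 450)
  r <- feature_distribution_test(obs, bg)
  E <- sum(obs) * bg / sum(bg)
  expect_equal(r$chi2, sum((obs - E)^2 / E), tolerance = 1e-9)
  expect_equal(r$df, 3L)
  ct <- suppressWarnings(stats::chisq.test(obs, p = bg / sum(bg)))
  expect_equal(r$chi2, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(r$p, unname(ct$p.value), tolerance = 1e-9)
})

test_that("the 2x3 Fisher enumeration is exact, normalized and matches 2x2 theory", {
  ## enumerated fixed-margin probabilities sum to 1
  g <- c(3, 5, 4); b <- c(20, 30, 10)
  tabs <- epichannels:::enumerate_margin_tables(sum(g), g + b)
  cs <- g + b
  lp <- apply(tabs, 1, function(x) sum(lchoose(cs, x)) - lchoose(sum(cs), sum(g)))
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)

  ## 2x2 reduction reproduces the classical hypergeometric two-sided p
  expect_equal(gene_response_fisher(c(3, 1, 0), c(1, 3, 0)), 34 / 70,
               tolerance = 1e-10)
  withr::with_seed(17, {
    for (i in 1:20) {
      a <- sample(0:6, 1); b2 <- sample(0:6, 1)
      c2 <- sample(0:6, 1); d <- sample(0:6, 1)
      if ((a + b2) == 0 || (c2 + d) == 0 || (a + c2) == 0 || (b2 + d) == 0) next
      expect_equal(gene_response_fisher(c(a, b2, 0), c(c2, d, 0)),
                   hyper_two_sided(a, b2, c2, d), tolerance = 1e-10)
    }
  })

  ## symmetric table: no table is strictly more extreme
  expect_equal(gene_response_fisher(c(1, 1, 0), c(1, 1, 0)), 1, tolerance = 1e-12)

  ## full 2x3 agrees with stats::fisher.test
  gg <- c(0, 12, 0); bb <- c(198, 914, 346)
  expect_equal(gene_response_fisher(gg, bb),
               stats::fisher.test(rbind(gg, bb))$p.value, tolerance = 1e-6)
})

test_that("per-gene response tables aggregate categories and directions", {
  channels <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
    category = c("inducible", "inducible", "stable", "inconclusive", "stable"),
    direction = c("expected", "opposite", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  feats <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                      gene_id = c("gA", "gA", "gA", "gB", NA),
                      stringsAsFactors = FALSE)
  tab <- gene_response_table(channels, feats, min_sites = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gene_id, "gA")
  expect_equal(tab$n_wild, 3L)
  expect_equal(tab$inducible, 2L)
  expect_equal(tab$expected, 1L)
  expect_equal(tab$opposite, 1L)
  expect_true(tab$fisher_p > 0 && tab$fisher_p <= 1)
})
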