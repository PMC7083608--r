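# Shared fixtures. The default end-to-end scenario is expensive, so it is
# generated once per test run and cached for every file that needs it.

.fixture_cache <- new.env(parent = emptyenv())

## full default scenario (5000 CpGs, 8 groups), decrease contrast only;
## FST/annotation/enrichment are exercised by their own dedicated tests
cached_default_scenario <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- suppressMessages(suppressWarnings(
      run_scenario(seed = 101, contrasts = "decrease",
                   do_fst = FALSE, do_annotate = FALSE,
                   do_enrich = FALSE, do_anova = FALSE)
    ))
  }
  .fixture_cache$default
}

## small deterministic methylation matrix: `rows` is a list of
## list(chrom, pos, cov = c(...), meth = c(...)) entries
mk_matrix <- function(rows, samples) {
  cov <- t(vapply(rows, function(r) as.integer(r$cov), integer(length(samples))))
  met <- t(vapply(rows, function(r) as.integer(r$meth), integer(length(samples))))
  meth_matrix(vapply(rows, `[[`, "", "chrom"),
              vapply(rows, function(r) r$pos, 1),
              samples, cov, met)
}

## random matrix with NA holes, for property-style filter tests
random_matrix <- function(n_sites = 60, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(c("chr1", "chr2"), n_sites, replace = TRUE)
    pos <- sample.int(1e5, n_sites)
    while (anyDuplicated(paste(chrom, pos))) pos <- sample.int(1e5, n_sites)
    cov <- matrix(rnbinom(n_sites * n_samples, mu = 25, size = 4),
                  n_sites, n_samples)
    cov[runif(length(cov)) < 0.15] <- NA
    cov[!is.na(cov) & cov == 0] <- 1
    met <- matrix(rbinom(length(cov), ifelse(is.na(cov), 0, cov), 0.4),
                  n_sites, n_samples)
    met[is.na(cov)] <- NA
    meth_matrix(chrom, pos, paste0("s", seq_len(n_samples)), cov, met)
  })
}

## tiny wild-style sample sheet: two groups, no families
mk_wild_sheet <- function(groups, n_per_group) {
  rows <- do.call(rbind, Map(function(g, n) {
    data.frame(sample = sprintf("%s_%02d", g, seq_len(n)), cohort = "wild",
               group = g, family = NA_character_, sex = "unknown",
               stringsAsFactors = FALSE)
  }, groups, n_per_group))
  sample_sheet(rows)
}

## design with only the two wild populations of one contrast
two_pop_design <- function(n1 = 15, n2 = 16) {
  data.frame(group = c("NYN6", "KIE20"), cohort = "wild",
             role = c("wild_low", "wild_ref"), n = c(n1, n2),
             stringsAsFactors = FALSE)
}

expect_same_matrix <- function(a, b) {
  expect_identical(a$sites, b$sites)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$methylated, b$methylated)
}
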