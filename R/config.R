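#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow common RRBS population-methylation practice: a Bonferroni-style
#' alpha of 0.0125 (0.05/4 pairwise comparisons) applied to q-values, a 15
#' percentage-point minimum weighted methylation difference, minimum coverage
#' of 10 reads, a 99.9th-percentile coverage cap, presence in at least nine
#' individuals per group, exclusion of the sex chromosome, C>T / G>A SNP
#' exclusion at GQ >= 20 and sample MAF >= 0.005, a promoter of 1500 bp
#' upstream / 500 bp downstream of the TSS, 10 kb TSS gene association,
#' +/- 5 kb FST windows with <= 60% missing genotypes and depth >= 5, 1000
#' enrichment replicates and 10000 FST randomizations.
#'
#' @param alpha_q significance threshold applied to q-values (strict `<`).
#' @param min_diff_pct minimum absolute weighted methylation difference, in
#'   percentage points.
#' @param min_cov minimum per-sample read coverage for a CpG to count as
#'   observed.
#' @param high_cov_percentile empirical coverage percentile above which
#'   entries are discarded (PCR-bias guard).
#' @param min_per_group minimum number of covered individuals per group.
#' @param sex_chrom chromosome label removed before testing.
#' @param snp_min_gq minimum mean genotype quality for a SNP to trigger CpG
#'   exclusion.
#' @param snp_min_maf minimum sample minor-allele frequency for a SNP to
#'   trigger CpG exclusion.
#' @param promoter_up,promoter_down promoter extent upstream/downstream of
#'   the TSS, in bp.
#' @param tss_assoc_bp maximum TSS distance for gene association of
#'   intergenic sites, in bp.
#' @param fst_halfwin_bp half-width of the FST window around a focal site.
#' @param fst_max_missing maximum fraction of missing genotypes per SNP
#'   (jointly across both populations).
#' @param fst_min_dp per-genotype depth below which a genotype is set
#'   missing in FST windows.
#' @param n_enrich_reps replicates for the category-enrichment
#'   randomization.
#' @param n_fst_boot replicates for the delta.mean.FST randomization test.
#' @param seed master RNG seed; per-stage streams are derived from it.
#' @param high_cov_scope `"sample"` (default) computes the percentile cap per
#'   sample; `"global"` uses one pooled threshold.
#' @param normalize_target `"median"` (default) scales sample coverages to
#'   the median of per-sample medians; `"max"` scales to the largest median.
#' @param fst_p_plus_one if `TRUE`, report (count+1)/(n+1) instead of the
#'   raw count/n randomization p (off by default; the raw ratio can be 0).
#' @param fst_bootstrap if `TRUE`, resample with replacement instead of
#'   permuting labels in [delta_mean_fst_test()].
#'
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_q = 0.0125,
                            min_diff_pct = 15,
                            min_cov = 10,
                            high_cov_percentile = 99.9,
                            min_per_group = 9,
                            sex_chrom = "chr19",
                            snp_min_gq = 20,
                            snp_min_maf = 0.005,
                            promoter_up = 1500,
                            promoter_down = 500,
                            tss_assoc_bp = 10000,
                            fst_halfwin_bp = 5000,
                            fst_max_missing = 0.6,
                            fst_min_dp = 5,
                            n_enrich_reps = 1000,
                            n_fst_boot = 10000,
                            seed = 1L,
                            high_cov_scope = c("sample", "global"),
                            normalize_target = c("median", "max"),
                            fst_p_plus_one = FALSE,
                            fst_bootstrap = FALSE) {
  cfg <- list(
    alpha_q = as.numeric(alpha_q),
    min_diff_pct = as.numeric(min_diff_pct),
    min_cov = as.integer(min_cov),
    high_cov_percentile = as.numeric(high_cov_percentile),
    min_per_group = as.integer(min_per_group),
    sex_chrom = as.character(sex_chrom),
    snp_min_gq = as.numeric(snp_min_gq),
    snp_min_maf = as.numeric(snp_min_maf),
    promoter_up = as.integer(promoter_up),
    promoter_down = as.integer(promoter_down),
    tss_assoc_bp = as.integer(tss_assoc_bp),
    fst_halfwin_bp = as.integer(fst_halfwin_bp),
    fst_max_missing = as.numeric(fst_max_missing),
    fst_min_dp = as.integer(fst_min_dp),
    n_enrich_reps = as.integer(n_enrich_reps),
    n_fst_boot = as.integer(n_fst_boot),
    seed = as.integer(seed),
    high_cov_scope = match.arg(high_cov_scope),
    normalize_target = match.arg(normalize_target),
    fst_p_plus_one = isTRUE(fst_p_plus_one),
    fst_bootstrap = isTRUE(fst_bootstrap)
  )
  stopifnot(
    cfg$alpha_q > 0, cfg$alpha_q < 1,
    cfg$min_diff_pct > 0, cfg$min_cov >= 1,
    cfg$high_cov_percentile > 0, cfg$high_cov_percentile <= 100,
    cfg$min_per_group >= 0,
    cfg$snp_min_gq > 0, cfg$snp_min_maf > 0,
    cfg$promoter_up > 0, cfg$promoter_down > 0,
    cfg$tss_assoc_bp > 0, cfg$fst_halfwin_bp > 0,
    cfg$fst_max_missing >= 0, cfg$fst_max_missing <= 1,
    cfg$fst_min_dp >= 0,
    cfg$n_enrich_reps > 0, cfg$n_fst_boot > 0
  )
  structure(cfg, class = c("analysis_config", "list"))
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML file mirrors [analysis_config()] field for field; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config an `analysis_config` object.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
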