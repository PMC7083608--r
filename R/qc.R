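#' Site/sample filtering chain for RRBS count matrices
#'
#' These six operations reproduce the standard RRBS quality chain in its
#' canonical order: minimum coverage, high-coverage percentile cap,
#' C>T/G>A SNP exclusion, between-sample coverage normalization, per-group
#' presence, and sex-chromosome removal. No filter ever increases a count,
#' and the count-dropping filters are idempotent (the percentile cap and the
#' integer-rounded normalization re-estimate from surviving data, so the
#' chain applies each exactly once). [filter_chain()] applies them in order
#' and returns an attrition report.
#'
#' @name qc_filtering
NULL

#' Remove low-coverage entries
#'
#' Entries with coverage below `min_cov` become absent; sites left absent in
#' every sample are dropped.
#'
#' @param M a [meth_matrix()].
#' @param min_cov minimum read coverage (inclusive: coverage == `min_cov`
#'   is retained).
#' @return filtered `meth_matrix`.
#' @export
filter_min_coverage <- function(M, min_cov = 10) {
  stopifnot(inherits(M, "meth_matrix"), min_cov >= 1)
  low <- !is.na(M$coverage) & M$coverage < min_cov
  M$coverage[low] <- NA_integer_
  M$methylated[low] <- NA_integer_
  res <- mm_drop_empty_sites(M)
  ec_log("filter_min_coverage: %d entries below %d removed, %d all-absent sites dropped",
         sum(low), min_cov, res$n_dropped)
  res$matrix
}

#' Cap extreme coverage at an empirical percentile
#'
#' Guards against PCR duplicates: entries with coverage strictly above the
#' sample's (default) or dataset's empirical percentile (linear-interpolation
#' definition, `stats::quantile` type 7) become absent.
#'
#' @param M a [meth_matrix()].
#' @param percentile percentile in (0, 100]; 100 removes nothing.
#' @param scope `"sample"` for a per-sample threshold, `"global"` for one
#'   pooled threshold.
#' @return filtered `meth_matrix`.
#' @export
filter_high_coverage <- function(M, percentile = 99.9,
                                 scope = c("sample", "global")) {
  stopifnot(inherits(M, "meth_matrix"), percentile > 0, percentile <= 100)
  scope <- match.arg(scope)
  n_removed <- 0L
  if (scope == "global") {
    pres <- !is.na(M$coverage)
    thr <- stats::quantile(M$coverage[pres], percentile / 100, names = FALSE)
    above <- pres & M$coverage > thr
    M$coverage[above] <- NA_integer_
    M$methylated[above] <- NA_integer_
    n_removed <- sum(above)
  } else {
    for (j in seq_along(M$samples)) {
      pres <- which(!is.na(M$coverage[, j]))
      if (length(pres) < 10) {
        warning(sprintf("filter_high_coverage: sample %s has <10 present sites; no cap applied",
                        M$samples[j]))
        next
      }
      thr <- stats::quantile(M$coverage[pres, j], percentile / 100, names = FALSE)
      above <- pres[M$coverage[pres, j] > thr]
      M$coverage[above, j] <- NA_integer_
      M$methylated[above, j] <- NA_integer_
      n_removed <- n_removed + length(above)
    }
  }
  res <- mm_drop_empty_sites(M)
  ec_log("filter_high_coverage: %d entries above the %.4g percentile removed, %d sites dropped",
         n_removed, percentile, res$n_dropped)
  res$matrix
}

#' Remove CpG sites overlapping C>T or G>A SNPs
#'
#' A polymorphic C>T at the CpG cytosine (or G>A at the guanine, pos+1)
#' mimics bisulfite conversion and corrupts the methylation call, so the
#' whole site is removed. Only variants passing mean genotype quality
#' >= `min_gq` (across genotyped samples) and sample minor-allele frequency
#' >= `min_maf` trigger removal. Variants with no GQ information never
#' trigger removal (their quality cannot be certified).
#'
#' @param M a [meth_matrix()].
#' @param V a [variant_table()], typically restricted to the wild reference
#'   cohort.
#' @param min_gq,min_maf thresholds (inclusive).
#' @return filtered `meth_matrix`.
#' @export
correct_snp_overlap <- function(M, V, min_gq = 20, min_maf = 0.005) {
  stopifnot(inherits(M, "meth_matrix"), inherits(V, "variant_table"))
  st <- variant_stats(V)
  pass <- !is.na(st$maf) & st$maf >= min_maf &
    !is.na(st$mean_gq) & st$mean_gq >= min_gq &
    nchar(V$ref) == 1L & nchar(V$alt) == 1L
  ct_keys <- site_key(V$chrom[pass & V$ref == "C" & V$alt == "T"],
                      V$pos[pass & V$ref == "C" & V$alt == "T"])
  ga_keys <- site_key(V$chrom[pass & V$ref == "G" & V$alt == "A"],
                      V$pos[pass & V$ref == "G" & V$alt == "A"])
  keys_c <- mm_site_keys(M)
  keys_g <- site_key(M$sites$chrom, M$sites$pos + 1L)
  hit <- keys_c %in% ct_keys | keys_g %in% ga_keys
  ec_log("correct_snp_overlap: %d CpG site(s) removed (C>T/G>A overlap)", sum(hit))
  mm_keep_sites(M, !hit)
}

#' Normalize coverage between samples
#'
#' Scales every sample's coverages so that per-sample median coverages agree:
#' sample `j` with median `m_j` gets factor `s_j = target / m_j` where the
#' target is the median (default) or maximum of the per-sample medians.
#' Counts are rescaled with half-away-from-zero rounding, present coverages
#' floored at 1, and methylated counts clamped into `[0, coverage]`; the
#' per-entry methylation fraction moves by at most `1/coverage'`.
#'
#' @param M a [meth_matrix()]; every sample must have at least one present
#'   site.
#' @param target `"median"` or `"max"` of the per-sample median coverages.
#' @return normalized `meth_matrix`.
#' @export
normalize_coverage <- function(M, target = c("median", "max")) {
  stopifnot(inherits(M, "meth_matrix"))
  target <- match.arg(target)
  med <- apply(M$coverage, 2, stats::median, na.rm = TRUE)
  if (anyNA(med) || any(med <= 0)) {
    stop("normalize_coverage: every sample needs >= 1 present site with coverage > 0")
  }
  tval <- if (target == "median") stats::median(med) else max(med)
  s <- tval / med
  for (j in seq_along(M$samples)) {
    pres <- !is.na(M$coverage[, j])
    cov0 <- M$coverage[pres, j]
    met0 <- M$methylated[pres, j]
    cov1 <- pmax(as.integer(round_half_away(s[j] * cov0)), 1L)
    met1 <- as.integer(round_half_away(cov1 * met0 / cov0))
    met1 <- pmin(pmax(met1, 0L), cov1)
    M$coverage[pres, j] <- cov1
    M$methylated[pres, j] <- met1
  }
  M
}

#' Keep sites covered in enough individuals of every group
#'
#' A site is retained iff it is present in at least `min_per_group` samples
#' of *every* listed group.
#'
#' @param M a [meth_matrix()].
#' @param sheet a [sample_sheet()].
#' @param groups group labels to enforce; a group with fewer total samples
#'   than `min_per_group` makes the filter unsatisfiable and errors.
#' @param min_per_group minimum present samples per group; 0 keeps all sites.
#' @return filtered `meth_matrix`.
#' @export
filter_presence <- function(M, sheet, groups, min_per_group = 9) {
  stopifnot(inherits(M, "meth_matrix"), length(groups) >= 1)
  keep <- rep(TRUE, n_sites(M))
  for (g in groups) {
    s <- sheet_samples(sheet, g, within = M$samples)
    if (min_per_group > 0 && length(s) < min_per_group) {
      stop(sprintf("filter_presence: group '%s' has %d samples < min_per_group %d (unsatisfiable)",
                   g, length(s), min_per_group))
    }
    if (min_per_group > 0) {
      keep <- keep &
        rowSums(!is.na(M$coverage[, s, drop = FALSE])) >= min_per_group
    }
  }
  ec_log("filter_presence: %d of %d sites retained (min %d per group, %d groups)",
         sum(keep), length(keep), min_per_group, length(groups))
  mm_keep_sites(M, keep)
}

#' Remove all sites on one chromosome
#'
#' Used to drop the sex chromosome, where sex-specific methylation would
#' confound population and treatment contrasts.
#'
#' @param M a [meth_matrix()].
#' @param chrom_label chromosome to remove; an absent label is a no-op with
#'   a warning.
#' @return filtered `meth_matrix`.
#' @export
drop_chromosome <- function(M, chrom_label) {
  stopifnot(inherits(M, "meth_matrix"))
  hit <- M$sites$chrom == chrom_label
  if (!any(hit)) {
    warning("drop_chromosome: label '", chrom_label, "' not present; no-op")
    return(M)
  }
  ec_log("drop_chromosome: %d site(s) on %s removed", sum(hit), chrom_label)
  mm_keep_sites(M, !hit)
}

#' Remove blacklisted sites from a DMS set
#'
#' Set difference on (chrom, pos). The blacklist is typically the DMS called
#' between the wild reference population and the experimental control group
#' — sites that differ between field and laboratory conditions are treated
#' as laboratory artifacts.
#'
#' @param dms_set data.frame with `chrom`, `pos` (e.g. the DMS rows of a
#'   [compare_groups()] table).
#' @param blacklist_dms data.frame with `chrom`, `pos`.
#' @return `dms_set` without blacklisted rows.
#' @export
drop_blacklist <- function(dms_set, blacklist_dms) {
  stopifnot(all(c("chrom", "pos") %in% names(dms_set)))
  if (is.null(blacklist_dms) || nrow(blacklist_dms) == 0) return(dms_set)
  drop <- site_key(dms_set$chrom, dms_set$pos) %in%
    site_key(blacklist_dms$chrom, blacklist_dms$pos)
  out <- dms_set[!drop, , drop = FALSE]
  rownames(out) <- NULL
  ec_log("drop_blacklist: %d of %d DMS removed", sum(drop), length(drop))
  out
}

#' Apply the full filter chain in its canonical order
#'
#' min coverage -> percentile cap -> SNP correction -> coverage
#' normalization -> per-group presence -> sex-chromosome removal.
#'
#' @param M raw merged [meth_matrix()].
#' @param sheet a [sample_sheet()].
#' @param variants optional [variant_table()] for SNP correction (skipped
#'   when `NULL`).
#' @param config an [analysis_config()].
#' @param groups groups for the presence filter; defaults to all groups in
#'   `sheet`.
#' @return list with `matrix` (filtered `meth_matrix`) and `report`
#'   (data.frame of sites/present entries after each step).
#' @export
filter_chain <- function(M, sheet, variants = NULL, config = analysis_config(),
                         groups = unique(sheet$group)) {
  step <- function(name, m) {
    data.frame(step = name, n_sites = n_sites(m),
               n_present = sum(!is.na(m$coverage)), stringsAsFactors = FALSE)
  }
  report <- step("input", M)
  M <- filter_min_coverage(M, config$min_cov)
  report <- rbind(report, step("min_coverage", M))
  M <- filter_high_coverage(M, config$high_cov_percentile, config$high_cov_scope)
  report <- rbind(report, step("high_coverage", M))
  if (!is.null(variants)) {
    M <- correct_snp_overlap(M, variants, config$snp_min_gq, config$snp_min_maf)
    report <- rbind(report, step("snp_correction", M))
  }
  M <- normalize_coverage(M, config$normalize_target)
  report <- rbind(report, step("normalize", M))
  M <- filter_presence(M, sheet, groups, config$min_per_group)
  report <- rbind(report, step("presence", M))
  if (config$sex_chrom %in% M$sites$chrom) {
    M <- drop_chromosome(M, config$sex_chrom)
  }
  report <- rbind(report, step("drop_sex_chrom", M))
  list(matrix = M, report = report)
}
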