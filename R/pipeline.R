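## groups taking part in one salinity contrast, looked up by design role
contrast_groups <- function(design, contrast = c("decrease", "increase")) {
  contrast <- match.arg(contrast)
  gof <- function(role) design$group[design$role == role]
  if (contrast == "decrease") {
    list(wild_ref = gof("wild_ref"), wild_target = gof("wild_low"),
         control = gof("control"), within = gof("within_low"),
         trans = gof("trans_low"))
  } else {
    list(wild_ref = gof("wild_ref"), wild_target = gof("wild_high"),
         control = gof("control"), within = gof("within_high"),
         trans = gof("trans_high"))
  }
}

## pop-DMS -> channel table + enrichment, shared by in-memory and file paths
build_channel_results <- function(wild_tab, within_tab, trans_tab,
                                  blacklist_tab, config, enrich_seed,
                                  do_enrich = TRUE) {
  popdms <- wild_tab[wild_tab$dms, c("chrom", "pos"), drop = FALSE]
  if (!is.null(blacklist_tab)) {
    blk <- blacklist_tab[blacklist_tab$dms, c("chrom", "pos"), drop = FALSE]
    popdms <- drop_blacklist(popdms, blk)
  }
  channels <- classify_channels(wild_tab, within_tab, trans_tab, config,
                                popdms = popdms)
  universe <- classify_channel(within_tab$q, within_tab$meth_diff,
                               trans_tab$q, trans_tab$meth_diff,
                               config$alpha_q, config$min_diff_pct)$category
  enrichment <- NULL
  if (do_enrich && nrow(channels) > 0 && !all(is.na(channels$category))) {
    obs <- table(factor(channels$category,
                        levels = c("inducible", "stable", "inconclusive")))
    enrichment <- enrichment_randomization(universe, obs,
                                           reps = config$n_enrich_reps,
                                           seed = enrich_seed,
                                           n_popdms = sum(obs))
  }
  list(popdms = popdms, channels = channels, universe = universe,
       enrichment = enrichment)
}

## direction x acclimation ANOVA input in long form (one row per site and
## acclimation level), restricted to inducible sites of one direction
anova_input <- function(channels, direction) {
  sel <- !is.na(channels$category) & channels$category == "inducible" &
    !is.na(channels$direction) & channels$direction == direction
  ch <- channels[sel, , drop = FALSE]
  data.frame(
    delta = c(ch$delta_meth_diff_within, ch$delta_meth_diff_trans),
    meth_direction = rep(ch$meth_direction, 2),
    acclimation = rep(c("within", "trans"), each = nrow(ch)),
    stringsAsFactors = FALSE
  )
}

run_contrast_anovas <- function(channels) {
  out <- list()
  for (dir in c("expected", "opposite")) {
    d <- anova_input(channels, dir)
    out[[dir]] <- tryCatch(
      acclimation_anova(d$delta, d$meth_direction, d$acclimation),
      error = function(e) list(flag = conditionMessage(e))
    )
  }
  out
}

#' Run the complete analysis on a synthetic scenario, in memory
#'
#' Generates a genome layout, methylomes, genotypes (with injected
#' CpG-overlapping SNPs), applies the filter chain, performs the wild,
#' blacklist and experimental comparisons, classifies the pop-DMS channels,
#' and (optionally) runs the enrichment randomization, the
#' direction-by-acclimation ANOVAs, the windowed-FST randomization and the
#' feature/gene annotation — one salinity contrast at a time. All
#' randomness derives from `seed` through fixed per-stage streams.
#'
#' @param seed master seed.
#' @param config an [analysis_config()].
#' @param design,params,n_families see [simulate_methylation()].
#' @param layout_args arguments for [generate_layout()] (minus `seed`).
#' @param inject_fraction CpG fraction receiving C>T/G>A SNPs.
#' @param contrasts which salinity contrasts to analyze.
#' @param do_blacklist,do_enrich,do_fst,do_annotate,do_anova stage toggles.
#' @return nested result list: simulation objects, filtered matrix, filter
#'   report, per-contrast tables and tests.
#' @export
run_scenario <- function(seed = 1, config = analysis_config(seed = seed),
                         design = default_design(), params = sim_params(),
                         layout_args = list(), n_families = 6,
                         inject_fraction = 0.01,
                         contrasts = c("decrease", "increase"),
                         do_blacklist = TRUE, do_enrich = TRUE,
                         do_fst = TRUE, do_annotate = TRUE, do_anova = TRUE) {
  layout <- do.call(generate_layout,
                    c(layout_args, list(seed = derive_seed(seed, 1))))
  sim <- simulate_methylation(layout, design, params,
                              seed = derive_seed(seed, 2),
                              n_families = n_families)
  V <- simulate_genotypes(layout, sim$sheet, sim$truth,
                          seed = derive_seed(seed, 3))
  V <- inject_cpg_snps(V, layout, inject_fraction,
                       seed = derive_seed(seed, 4))
  fc <- filter_chain(sim$matrix, sim$sheet, V, config)
  M <- fc$matrix
  sheet <- sim$sheet
  blacklist_tab <- NULL
  if (do_blacklist) {
    g <- contrast_groups(design, "decrease")
    blacklist_tab <- compare_groups(M, sheet, g$wild_ref, g$control, config)
  }
  res_contrasts <- list()
  for (k in seq_along(contrasts)) {
    ct <- contrasts[k]
    g <- contrast_groups(design, ct)
    wild_tab <- compare_groups(M, sheet, g$wild_ref, g$wild_target, config)
    within_tab <- compare_groups(M, sheet, g$control, g$within, config)
    trans_tab <- compare_groups(M, sheet, g$control, g$trans, config)
    bc <- build_channel_results(wild_tab, within_tab, trans_tab,
                                blacklist_tab, config,
                                enrich_seed = derive_seed(seed, 10 + k),
                                do_enrich = do_enrich)
    out <- list(groups = g, wild = wild_tab, within = within_tab,
                trans = trans_tab, popdms = bc$popdms,
                channels = bc$channels, universe = bc$universe,
                enrichment = bc$enrichment)
    if (do_anova) out$anova <- run_contrast_anovas(bc$channels)
    if (do_fst) {
      pop1 <- sheet_samples(sheet, g$wild_ref)
      pop2 <- sheet_samples(sheet, g$wild_target)
      out$fst_windows <- fst_windows(bc$channels, V, pop1, pop2, config)
      e <- out$fst_windows$mean_fst[out$fst_windows$direction == "expected"]
      o <- out$fst_windows$mean_fst[out$fst_windows$direction == "opposite"]
      out$delta_fst <- if (sum(!is.na(e)) && sum(!is.na(o))) {
        delta_mean_fst_test(e, o, n_boot = config$n_fst_boot,
                            seed = derive_seed(seed, 20 + k),
                            bootstrap = config$fst_bootstrap,
                            plus_one = config$fst_p_plus_one)
      }
    }
    if (do_annotate && nrow(layout$genes$genes) > 0) {
      feats_bg <- associate_gene(
        annotate_features(M$sites, layout$genes,
                          config$promoter_up, config$promoter_down),
        config$tss_assoc_bp
      )
      idx <- match(site_key(bc$popdms$chrom, bc$popdms$pos),
                   site_key(feats_bg$chrom, feats_bg$pos))
      out$features_dms <- feats_bg[idx, , drop = FALSE]
      out$feature_test <- if (nrow(out$features_dms) > 0) {
        feature_distribution_test(out$features_dms$feature, feats_bg$feature)
      }
      out$gene_table <- gene_response_table(bc$channels, out$features_dms)
    }
    res_contrasts[[ct]] <- out
  }
  list(seed = seed, config = config, layout = layout, sim = sim,
       variants = V, filtered = M, filter_report = fc$report,
       blacklist = blacklist_tab, contrasts = res_contrasts)
}

#' Ground-truth recovery metrics for a scenario run
#'
#' Compares one contrast of a [run_scenario()] result against the planted
#' truth: what fraction of planted population effects survived as pop-DMS,
#' how often recovered truly-inducible sites were classified inducible, and
#' how often their direction label matches the planted one.
#'
#' @param res a [run_scenario()] result.
#' @param contrast contrast name present in `res$contrasts`.
#' @return list `recovery_pct`, `category_accuracy_pct`,
#'   `direction_accuracy_pct`, `n_planted`, `n_recovered`,
#'   `n_inducible_recovered`.
#' @export
scenario_metrics <- function(res, contrast = "decrease") {
  truth <- res$sim$truth
  ct <- res$contrasts[[contrast]]
  stopifnot(!is.null(ct))
  pop_keys <- site_key(ct$popdms$chrom, ct$popdms$pos)
  planted <- truth[truth$class != "null", ]
  planted_keys <- site_key(planted$chrom, planted$pos)
  recovered <- planted_keys %in% pop_keys
  ch_keys <- site_key(ct$channels$chrom, ct$channels$pos)
  ind <- planted$class %in% c("inducible-expected", "inducible-opposite")
  ind_rec <- which(ind & recovered)
  m <- match(planted_keys[ind_rec], ch_keys)
  cat_ok <- ct$channels$category[m] == "inducible"
  want_dir <- ifelse(planted$class[ind_rec] == "inducible-expected",
                     "expected", "opposite")
  have_dir <- ct$channels$direction[m]
  dir_sel <- !is.na(cat_ok) & cat_ok & have_dir %in% c("expected", "opposite")
  list(
    recovery_pct = 100 * mean(recovered),
    category_accuracy_pct = 100 * mean(cat_ok, na.rm = TRUE),
    direction_accuracy_pct = 100 * mean(have_dir[dir_sel] == want_dir[dir_sel]),
    n_planted = nrow(planted),
    n_recovered = sum(recovered),
    n_inducible_recovered = length(ind_rec)
  )
}

## -- file-based pipeline ----------------------------------------------------

pl_path <- function(outdir, ...) file.path(outdir, ...)

pl_require <- function(outdir, files, stage_needed) {
  miss <- files[!file.exists(pl_path(outdir, files))]
  if (length(miss)) {
    stop(sprintf("missing artifact(s) %s: run stage '%s' first",
                 paste(miss, collapse = ", "), stage_needed))
  }
}

pl_provenance <- function(outdir, stage, seed, inputs, outputs) {
  all_files <- c(inputs, outputs)
  md5 <- tools::md5sum(pl_path(outdir, all_files))
  names(md5) <- all_files
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         config = unname(tools::md5sum(pl_path(outdir, "config.yaml"))),
         inputs = as.list(md5[inputs]), outputs = as.list(md5[outputs])),
    pl_path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE
  )
}

#' Run the pipeline against on-disk artifacts, stage by stage
#'
#' Orchestrates simulate -> filter -> dms -> classify -> fst -> annotate ->
#' report under `outdir`. Every stage reads only files written by earlier
#' stages (a missing artifact raises an error naming the stage to run),
#' writes its result tables as TSV/JSON, and records a provenance JSON with
#' the seed and md5 checksums of its inputs and outputs. Reruns with the
#' same seed and configuration reproduce every table byte for byte.
#'
#' @param outdir artifact directory (created if needed).
#' @param seed master seed (all per-stage streams derive from it).
#' @param config an [analysis_config()].
#' @param stages subset of
#'   `c("simulate","filter","dms","classify","fst","annotate","report")`.
#' @param design,params,layout_args,n_families,inject_fraction scenario
#'   controls for the `simulate` stage.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(outdir, seed = 1, config = analysis_config(seed = seed),
                         stages = c("simulate", "filter", "dms", "classify",
                                    "fst", "annotate", "report"),
                         design = default_design(), params = sim_params(),
                         layout_args = list(), n_families = 6,
                         inject_fraction = 0.01) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_analysis_config(config, pl_path(outdir, "config.yaml"))
  cov_files <- function(sheet) file.path("sim", paste0(sheet$sample, ".cov"))
  contrast_names <- c("decrease", "increase")

  if ("simulate" %in% stages) {
    layout <- do.call(generate_layout,
                      c(layout_args, list(seed = derive_seed(seed, 1))))
    sim <- simulate_methylation(layout, design, params,
                                seed = derive_seed(seed, 2),
                                n_families = n_families)
    V <- simulate_genotypes(layout, sim$sheet, sim$truth,
                            seed = derive_seed(seed, 3))
    V <- inject_cpg_snps(V, layout, inject_fraction,
                         seed = derive_seed(seed, 4))
    write_scenario(pl_path(outdir, "sim"), sim, V)
    pl_provenance(outdir, "simulate", seed, character(0),
                  c("sim/samples.tsv", "sim/variants.vcf", "sim/genes.gff3",
                    "sim/truth_sites.tsv"))
  }

  if ("filter" %in% stages) {
    pl_require(outdir, "sim/samples.tsv", "simulate")
    sc <- read_scenario(pl_path(outdir, "sim"))
    fc <- filter_chain(sc$matrix, sc$sheet, sc$variants, config)
    write_meth_matrix(fc$matrix, pl_path(outdir, "filtered_matrix.tsv"))
    write_results_table(fc$report, pl_path(outdir, "filter_report.tsv"))
    pl_provenance(outdir, "filter", seed, cov_files(sc$sheet),
                  c("filtered_matrix.tsv", "filter_report.tsv"))
  }

  if ("dms" %in% stages) {
    pl_require(outdir, c("filtered_matrix.tsv", "sim/samples.tsv"), "filter")
    M <- read_meth_matrix(pl_path(outdir, "filtered_matrix.tsv"))
    sheet <- read_sample_sheet(pl_path(outdir, "sim", "samples.tsv"))
    outs <- character(0)
    gdec <- contrast_groups(design, "decrease")
    blk <- compare_groups(M, sheet, gdec$wild_ref, gdec$control, config)
    write_results_table(blk, pl_path(outdir, "dms_blacklist.tsv"))
    outs <- c(outs, "dms_blacklist.tsv")
    for (ct in contrast_names) {
      g <- contrast_groups(design, ct)
      for (nm in c("wild", "within", "trans")) {
        tab <- switch(nm,
                      wild = compare_groups(M, sheet, g$wild_ref, g$wild_target, config),
                      within = compare_groups(M, sheet, g$control, g$within, config),
                      trans = compare_groups(M, sheet, g$control, g$trans, config))
        f <- sprintf("dms_%s_%s.tsv", nm, ct)
        write_results_table(tab, pl_path(outdir, f))
        outs <- c(outs, f)
      }
    }
    pl_provenance(outdir, "dms", seed, "filtered_matrix.tsv", outs)
  }

  if ("classify" %in% stages) {
    need <- c("dms_blacklist.tsv",
              sprintf("dms_%s_%s.tsv",
                      rep(c("wild", "within", "trans"), 2),
                      rep(contrast_names, each = 3)))
    pl_require(outdir, need, "dms")
    blk <- read_results_table(pl_path(outdir, "dms_blacklist.tsv"))
    summary <- list()
    outs <- character(0)
    for (k in seq_along(contrast_names)) {
      ct <- contrast_names[k]
      wild_tab <- read_results_table(pl_path(outdir, sprintf("dms_wild_%s.tsv", ct)))
      within_tab <- read_results_table(pl_path(outdir, sprintf("dms_within_%s.tsv", ct)))
      trans_tab <- read_results_table(pl_path(outdir, sprintf("dms_trans_%s.tsv", ct)))
      bc <- build_channel_results(wild_tab, within_tab, trans_tab, blk,
                                  config, derive_seed(seed, 10 + k))
      f <- sprintf("channels_%s.tsv", ct)
      write_results_table(bc$channels, pl_path(outdir, f))
      outs <- c(outs, f)
      counts <- table(factor(bc$channels$category,
                             levels = c("inducible", "stable", "inconclusive")))
      dirs <- table(factor(bc$channels$direction[
        !is.na(bc$channels$category) & bc$channels$category == "inducible"],
        levels = c("expected", "opposite")))
      summary[[ct]] <- list(
        n_popdms = nrow(bc$channels),
        counts = as.list(counts), directions = as.list(dirs),
        enrichment = if (!is.null(bc$enrichment)) {
          bc$enrichment[c("observed", "expected", "chi2", "df", "p")]
        }
      )
    }
    jsonlite::write_json(summary, pl_path(outdir, "classify_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pl_provenance(outdir, "classify", seed, need,
                  c(outs, "classify_summary.json"))
  }

  if ("fst" %in% stages) {
    pl_require(outdir, c("channels_decrease.tsv", "channels_increase.tsv"),
               "classify")
    pl_require(outdir, "sim/variants.vcf", "simulate")
    V <- read_vcf_minimal(pl_path(outdir, "sim", "variants.vcf"))
    sheet <- read_sample_sheet(pl_path(outdir, "sim", "samples.tsv"))
    fstsum <- list()
    outs <- character(0)
    for (k in seq_along(contrast_names)) {
      ct <- contrast_names[k]
      g <- contrast_groups(design, ct)
      channels <- read_results_table(pl_path(outdir, sprintf("channels_%s.tsv", ct)))
      fw <- fst_windows(channels, V, sheet_samples(sheet, g$wild_ref),
                        sheet_samples(sheet, g$wild_target), config)
      f <- sprintf("fst_windows_%s.tsv", ct)
      write_results_table(fw, pl_path(outdir, f))
      outs <- c(outs, f)
      e <- fw$mean_fst[fw$direction == "expected"]
      o <- fw$mean_fst[fw$direction == "opposite"]
      fstsum[[ct]] <- if (sum(!is.na(e)) && sum(!is.na(o))) {
        t <- delta_mean_fst_test(e, o, n_boot = config$n_fst_boot,
                                 seed = derive_seed(seed, 20 + k),
                                 bootstrap = config$fst_bootstrap,
                                 plus_one = config$fst_p_plus_one)
        list(delta_mean_fst = t$delta, p_one_tailed = t$p_one_tailed,
             n_expected = sum(!is.na(e)), n_opposite = sum(!is.na(o)))
      }
    }
    jsonlite::write_json(fstsum, pl_path(outdir, "fst_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pl_provenance(outdir, "fst", seed,
                  c("channels_decrease.tsv", "channels_increase.tsv"),
                  c(outs, "fst_summary.json"))
  }

  if ("annotate" %in% stages) {
    pl_require(outdir, c("channels_decrease.tsv", "channels_increase.tsv"),
               "classify")
    pl_require(outdir, c("sim/genes.gff3", "filtered_matrix.tsv"), "filter")
    genes <- read_gff_genes(pl_path(outdir, "sim", "genes.gff3"))
    M <- read_meth_matrix(pl_path(outdir, "filtered_matrix.tsv"))
    feats_bg <- associate_gene(
      annotate_features(M$sites, genes, config$promoter_up,
                        config$promoter_down),
      config$tss_assoc_bp
    )
    ann <- list()
    outs <- character(0)
    for (ct in contrast_names) {
      channels <- read_results_table(pl_path(outdir, sprintf("channels_%s.tsv", ct)))
      idx <- match(site_key(channels$chrom, channels$pos),
                   site_key(feats_bg$chrom, feats_bg$pos))
      fd <- feats_bg[idx, , drop = FALSE]
      f1 <- sprintf("features_%s.tsv", ct)
      write_results_table(fd, pl_path(outdir, f1))
      gt <- gene_response_table(channels, fd)
      f2 <- sprintf("genes_%s.tsv", ct)
      write_results_table(gt, pl_path(outdir, f2))
      outs <- c(outs, f1, f2)
      ann[[ct]] <- if (nrow(fd) > 0) {
        ft <- feature_distribution_test(fd$feature, feats_bg$feature)
        list(feature_chi2 = ft$chi2, df = ft$df, p = ft$p)
      }
    }
    jsonlite::write_json(ann, pl_path(outdir, "annotate_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pl_provenance(outdir, "annotate", seed,
                  c("channels_decrease.tsv", "channels_increase.tsv"),
                  c(outs, "annotate_summary.json"))
  }

  if ("report" %in% stages) {
    pl_require(outdir, "classify_summary.json", "classify")
    rep <- list(seed = seed,
                classify = jsonlite::read_json(pl_path(outdir, "classify_summary.json")))
    for (f in c("fst_summary.json", "annotate_summary.json")) {
      if (file.exists(pl_path(outdir, f))) {
        rep[[sub("_summary\\.json$", "", f)]] <- jsonlite::read_json(pl_path(outdir, f))
      }
    }
    if (file.exists(pl_path(outdir, "filter_report.tsv"))) {
      rep$filter <- read_results_table(pl_path(outdir, "filter_report.tsv"))
    }
    jsonlite::write_json(rep, pl_path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pl_provenance(outdir, "report", seed, "classify_summary.json", "report.json")
  }

  invisible(outdir)
}
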