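#' Default study design for synthetic scenarios
#'
#' Three wild populations along the salinity cline (low 6 PSU, reference
#' 20 PSU, high 33 PSU; n = 15/16/15) and five experimental groups bred
#' from the reference population (control at 20 PSU, within- and
#' transgenerational acclimation to 6 and 33 PSU; n = 12 each) with a
#' split-clutch family structure shared across treatment groups.
#'
#' @return data.frame `group`, `cohort`, `role`, `n`.
#' @export
default_design <- function() {
  data.frame(
    group = c("NYN6", "KIE20", "SYL33",
              "ctrl20", "within6", "trans6", "within33", "trans33"),
    cohort = c(rep("wild", 3), rep("experimental", 5)),
    role = c("wild_low", "wild_ref", "wild_high",
             "control", "within_low", "trans_low",
             "within_high", "trans_high"),
    n = c(15L, 16L, 15L, 12L, 12L, 12L, 12L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' Defaults encode the statistical structure the pipeline assumes: bimodal
#' per-CpG baseline methylation (`0.5*Beta(0.5,8) + 0.5*Beta(8,0.5)`),
#' negative-binomial coverage (mean 30, dispersion 5, floored at 1),
#' beta-binomial methylated counts with intra-sample correlation
#' `rho = 0.01`, family effects on the logit scale (sd 0.3), 100 planted
#' population effects of +/-30 pp (40 inducible-expected, 20
#' inducible-opposite, 20 with a sub-threshold 10 pp induced effect, 20
#' purely stable), and a within-generation induction attenuated by
#' `g_within = 0.6` so transgenerational groups sit closer to the wild
#' difference.
#'
#' @param mu_coverage,size_coverage negative-binomial coverage mean and
#'   dispersion.
#' @param rho intra-sample (beta-binomial) correlation; 0 gives pure
#'   binomial counts.
#' @param sigma_family family random-effect sd on the logit scale (per site
#'   and family).
#' @param mix_weight,beta_a,beta_b baseline Beta-mixture parameters
#'   (`mix_weight*Beta(a,b) + (1-mix_weight)*Beta(b,a)`).
#' @param n_inducible_expected,n_inducible_opposite,n_inconclusive,n_stable_only
#'   planted class sizes (their sum is the number of population effects).
#' @param delta_wild_pp planted wild difference (pp, random sign).
#' @param g_within attenuation of the within-generation induced effect.
#' @param delta_inconclusive_pp induced effect of inconclusive-class sites.
#' @param planted_pi0_range baseline methylation range for planted sites
#'   (kept intermediate so +/-30 pp fits in `[clip_lo, clip_hi]`).
#' @param clip_lo,clip_hi clipping bounds for group means.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(mu_coverage = 30, size_coverage = 5, rho = 0.01,
                       sigma_family = 0.3, mix_weight = 0.5,
                       beta_a = 0.5, beta_b = 8,
                       n_inducible_expected = 40, n_inducible_opposite = 20,
                       n_inconclusive = 20, n_stable_only = 20,
                       delta_wild_pp = 30, g_within = 0.6,
                       delta_inconclusive_pp = 10,
                       planted_pi0_range = c(0.35, 0.65),
                       clip_lo = 0.01, clip_hi = 0.99) {
  p <- as.list(environment())
  stopifnot(p$mu_coverage > 0, p$size_coverage > 0, p$rho >= 0, p$rho < 1,
            p$sigma_family >= 0, p$g_within > 0, p$g_within <= 1,
            p$clip_lo > 0, p$clip_hi < 1, p$clip_lo < p$clip_hi)
  structure(p, class = c("sim_params", "list"))
}

#' Generate a synthetic genome layout
#'
#' Uniformly placed, collision-free CpG positions (even coordinates, so a
#' CpG's C at `pos` and G at `pos+1` never collide with a neighbour),
#' non-overlapping genes with 2-8 exons, and one chromosome labelled as the
#' sex chromosome (`chr19`, a quarter the autosome length).
#'
#' @param n_chroms number of chromosomes (the last is the sex chromosome).
#' @param chrom_len autosome length in bp.
#' @param n_cpg total CpG count (allocated by chromosome length).
#' @param n_genes total gene count.
#' @param seed RNG seed; the layout is a pure function of its arguments.
#' @return list of class `genome_layout`: `chroms` (data.frame `chrom`,
#'   `length`, `is_sex`), `cpgs` (data.frame `chrom`, `pos`), `genes`
#'   (a [gene_models()]).
#' @export
generate_layout <- function(n_chroms = 3, chrom_len = 1e6, n_cpg = 5000,
                            n_genes = 120, seed = 1) {
  stopifnot(n_chroms >= 2, chrom_len > 1000, n_cpg > 0, n_genes >= 0)
  chroms <- data.frame(
    chrom = c(paste0("chr", seq_len(n_chroms - 1)), "chr19"),
    length = c(rep(chrom_len, n_chroms - 1), round(chrom_len / 4)),
    is_sex = c(rep(FALSE, n_chroms - 1), TRUE),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    total_len <- sum(chroms$length)
    n_per <- round(n_cpg * chroms$length / total_len)
    n_per[1] <- n_per[1] + (n_cpg - sum(n_per))
    cpgs <- NULL
    for (i in seq_len(nrow(chroms))) {
      slots <- seq(2L, chroms$length[i] - 2L, by = 2L)
      if (n_per[i] > length(slots)) stop("CpG density infeasible for ",
                                         chroms$chrom[i])
      pos <- sort(sample(slots, n_per[i]))
      cpgs <- rbind(cpgs, data.frame(chrom = chroms$chrom[i], pos = pos,
                                     stringsAsFactors = FALSE))
    }
    genes_df <- NULL
    exons_df <- NULL
    if (n_genes > 0) {
      ng_per <- round(n_genes * chroms$length / total_len)
      ng_per[1] <- ng_per[1] + (n_genes - sum(ng_per))
      gidx <- 0L
      for (i in seq_len(nrow(chroms))) {
        ng <- ng_per[i]
        if (ng <= 0) next
        ## one gene per equal slice keeps genes non-overlapping by design
        slice <- floor(chroms$length[i] / ng)
        if (slice < 3000) stop("gene density infeasible for ", chroms$chrom[i])
        for (k in seq_len(ng)) {
          gidx <- gidx + 1L
          lo <- (k - 1L) * slice + 1L
          glen <- sample(2000:min(10000, slice - 200), 1)
          gstart <- lo + sample.int(slice - glen - 100, 1)
          gend <- gstart + glen - 1L
          gid <- sprintf("G%05d", gidx)
          strand <- sample(c("+", "-"), 1)
          n_ex <- sample(2:8, 1)
          brk <- sort(sample((gstart + 1L):(gend - 1L), 2L * n_ex - 2L))
          ex_start <- c(gstart, brk[seq(2, length(brk), by = 2)])
          ex_end <- c(brk[seq(1, length(brk), by = 2)], gend)
          genes_df <- rbind(genes_df, data.frame(
            gene_id = gid, chrom = chroms$chrom[i], strand = strand,
            start = gstart, end = gend, stringsAsFactors = FALSE
          ))
          exons_df <- rbind(exons_df, data.frame(
            gene_id = gid, chrom = chroms$chrom[i],
            start = ex_start, end = ex_end, stringsAsFactors = FALSE
          ))
        }
      }
    }
    gm <- if (is.null(genes_df)) {
      gene_models(data.frame(gene_id = character(0), chrom = character(0),
                             strand = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE))
    } else {
      gene_models(genes_df, exons_df)
    }
    structure(list(chroms = chroms, cpgs = cpgs, genes = gm),
              class = c("genome_layout", "list"))
  })
}

## group role -> planted effect (pp) lookup used by simulate_methylation
role_delta <- function(role, truth) {
  switch(role,
         wild_low = truth$delta_wild,
         within_low = truth$delta_within,
         trans_low = truth$delta_trans,
         ## reference, high-salinity wild and high-salinity treatment groups
         ## carry no planted effects in the default single-contrast truth
         rep(0, nrow(truth)))
}

#' Simulate an RRBS methylation matrix with planted ground truth
#'
#' Baseline methylation comes from a bimodal Beta mixture; planted sites
#' get an intermediate baseline so the effects fit inside the probability
#' scale. Planted classes: `pop-effect` (wild difference only),
#' `inducible-expected` (induced change with the wild sign; the
#' within-generation effect is attenuated by `g_within`, the
#' transgenerational effect matches the wild difference),
#' `inducible-opposite` (same magnitudes, opposite sign) and
#' `inconclusive-effect` (significant but sub-threshold induced change).
#' Family effects act on the logit scale and are shared across treatment
#' groups (split-clutch design); coverage is negative-binomial and
#' methylated counts beta-binomial.
#'
#' @param layout a [generate_layout()] result.
#' @param design a [default_design()]-style data.frame.
#' @param params a [sim_params()] list.
#' @param seed RNG seed; output is byte-identical for identical inputs.
#' @param n_families number of split-clutch families in the experimental
#'   cohort.
#' @return list of class `sim_scenario`: `matrix` ([meth_matrix()]),
#'   `sheet` ([sample_sheet()]), `truth` (per-site data.frame), `layout`.
#' @export
simulate_methylation <- function(layout, design = default_design(),
                                 params = sim_params(), seed = 1,
                                 n_families = 6) {
  stopifnot(inherits(layout, "genome_layout"))
  cp <- layout$cpgs
  ns <- nrow(cp)
  n_planted <- params$n_inducible_expected + params$n_inducible_opposite +
    params$n_inconclusive + params$n_stable_only
  withr::with_seed(seed, {
    ## ground truth ---------------------------------------------------------
    autosomal <- which(!cp$chrom %in% layout$chroms$chrom[layout$chroms$is_sex])
    if (n_planted > length(autosomal)) stop("more planted sites than autosomal CpGs")
    cls <- rep("null", ns)
    planted <- if (n_planted > 0) sample(autosomal, n_planted) else integer(0)
    cls[planted] <- rep(c("inducible-expected", "inducible-opposite",
                          "inconclusive-effect", "pop-effect"),
                        c(params$n_inducible_expected,
                          params$n_inducible_opposite,
                          params$n_inconclusive, params$n_stable_only))
    pi0 <- ifelse(stats::runif(ns) < params$mix_weight,
                  stats::rbeta(ns, params$beta_a, params$beta_b),
                  stats::rbeta(ns, params$beta_b, params$beta_a))
    pi0[planted] <- stats::runif(length(planted),
                                 params$planted_pi0_range[1],
                                 params$planted_pi0_range[2])
    sgn <- sample(c(-1, 1), ns, replace = TRUE)
    dwild <- ifelse(cls == "null", 0, sgn * params$delta_wild_pp)
    dwithin <- rep(0, ns)
    dtrans <- rep(0, ns)
    i <- cls == "inducible-expected"
    dwithin[i] <- params$g_within * dwild[i]
    dtrans[i] <- dwild[i]
    i <- cls == "inducible-opposite"
    dwithin[i] <- -params$g_within * dwild[i]
    dtrans[i] <- -dwild[i]
    i <- cls == "inconclusive-effect"
    dwithin[i] <- sign(dwild[i]) * params$delta_inconclusive_pp
    dtrans[i] <- dwithin[i]
    truth <- data.frame(chrom = cp$chrom, pos = cp$pos, pi0 = pi0,
                        class = cls, delta_wild = dwild,
                        delta_within = dwithin, delta_trans = dtrans,
                        stringsAsFactors = FALSE)

    ## sample sheet ---------------------------------------------------------
    rows <- NULL
    for (r in seq_len(nrow(design))) {
      g <- design$group[r]
      n <- design$n[r]
      fam <- if (design$cohort[r] == "experimental") {
        paste0("F", rep_len(seq_len(n_families), n))
      } else {
        rep(NA_character_, n)
      }
      rows <- rbind(rows, data.frame(
        sample = sprintf("%s_%02d", g, seq_len(n)),
        cohort = design$cohort[r], group = g, family = fam,
        sex = rep_len(c("F", "M"), n), stringsAsFactors = FALSE
      ))
    }
    sheet <- sample_sheet(rows)

    ## family effects on the logit scale, shared across treatment groups ----
    b_fam <- matrix(stats::rnorm(ns * n_families, 0, params$sigma_family),
                    ns, n_families,
                    dimnames = list(NULL, paste0("F", seq_len(n_families))))

    ## counts ---------------------------------------------------------------
    n_clipped <- 0L
    cov <- matrix(NA_integer_, ns, nrow(sheet))
    met <- matrix(NA_integer_, ns, nrow(sheet))
    role_of <- stats::setNames(design$role, design$group)
    for (j in seq_len(nrow(sheet))) {
      delta <- role_delta(role_of[[sheet$group[j]]], truth)
      mu_raw <- pi0 + delta / 100
      n_clipped <- n_clipped + sum(mu_raw < params$clip_lo |
                                     mu_raw > params$clip_hi)
      mu <- pmin(pmax(mu_raw, params$clip_lo), params$clip_hi)
      if (!is.na(sheet$family[j]) && params$sigma_family > 0) {
        mu <- stats::plogis(stats::qlogis(mu) + b_fam[, sheet$family[j]])
      }
      cv <- pmax(stats::rnbinom(ns, size = params$size_coverage,
                                mu = params$mu_coverage), 1L)
      if (params$rho > 0) {
        shp <- (1 - params$rho) / params$rho
        mu_b <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
        pj <- stats::rbeta(ns, mu_b * shp, (1 - mu_b) * shp)
      } else {
        pj <- mu
      }
      cov[, j] <- cv
      met[, j] <- stats::rbinom(ns, cv, pj)
    }
    if (n_clipped > 0) {
      ec_log("simulate_methylation: %d group-mean value(s) clipped into [%.2f, %.2f]",
             n_clipped, params$clip_lo, params$clip_hi)
    }
    M <- meth_matrix(cp$chrom, cp$pos, sheet$sample, cov, met)
    structure(list(matrix = M, sheet = sheet, truth = truth, layout = layout),
              class = c("sim_scenario", "list"))
  })
}

#' Simulate population genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); each wild
#' population draws its frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` and genotypes follow Hardy-Weinberg.
#' Background SNPs are placed uniformly (never on a CpG C or G); every
#' planted inducible site is additionally guaranteed `snps_per_site` SNPs
#' within the FST window, drawn with a class-specific F so
#' inducible-opposite neighbourhoods are more differentiated than
#' inducible-expected ones.
#'
#' @param layout a [generate_layout()] result.
#' @param sheet the scenario [sample_sheet()] (wild samples are genotyped).
#' @param truth per-site truth (for class-specific window SNPs); `NULL`
#'   plants background SNPs only.
#' @param n_snps background SNP count.
#' @param F_by_class named differentiation targets: `background`,
#'   `inducible-expected`, `inducible-opposite`.
#' @param snps_per_site guaranteed SNPs within the window of each planted
#'   inducible site.
#' @param window_bp half-width of that window.
#' @param dp_mean Poisson mean of the simulated depth; `gq` fixed genotype
#'   quality.
#' @param gq fixed genotype quality written to every call.
#' @param seed RNG seed.
#' @return a [variant_table()] with attribute `snp_truth` (per-SNP class,
#'   F and per-population frequencies).
#' @export
simulate_genotypes <- function(layout, sheet, truth = NULL, n_snps = 2000,
                               F_by_class = c(background = 0.10,
                                              `inducible-expected` = 0.02,
                                              `inducible-opposite` = 0.25),
                               snps_per_site = 10, window_bp = 5000,
                               dp_mean = 20, gq = 60, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), all(F_by_class > 0),
            all(F_by_class < 1))
  wild <- sheet[sheet$cohort == "wild", ]
  pops <- split(wild$sample, wild$group)
  forbidden <- c(site_key(layout$cpgs$chrom, layout$cpgs$pos),
                 site_key(layout$cpgs$chrom, layout$cpgs$pos + 1L))
  withr::with_seed(seed, {
    chrom <- character(0)
    pos <- integer(0)
    fval <- numeric(0)
    sclass <- character(0)
    ## background SNPs, length-proportional across chromosomes
    total_len <- sum(layout$chroms$length)
    for (i in seq_len(nrow(layout$chroms))) {
      nb <- round(n_snps * layout$chroms$length[i] / total_len)
      cand <- sample.int(layout$chroms$length[i] - 1L, min(3 * nb + 50,
                                                           layout$chroms$length[i] - 1L))
      cand <- cand[!(site_key(layout$chroms$chrom[i], cand) %in% forbidden)]
      cand <- cand[seq_len(min(nb, length(cand)))]
      chrom <- c(chrom, rep(layout$chroms$chrom[i], length(cand)))
      pos <- c(pos, cand)
      fval <- c(fval, rep(F_by_class[["background"]], length(cand)))
      sclass <- c(sclass, rep("background", length(cand)))
    }
    ## guaranteed window SNPs around planted inducible sites
    if (!is.null(truth)) {
      ind <- truth[truth$class %in% c("inducible-expected",
                                      "inducible-opposite"), ]
      for (i in seq_len(nrow(ind))) {
        ch <- ind$chrom[i]
        clen <- layout$chroms$length[match(ch, layout$chroms$chrom)]
        lo <- max(1L, ind$pos[i] - window_bp)
        hi <- min(clen - 1L, ind$pos[i] + window_bp)
        cand <- sample(lo:hi, min(3 * snps_per_site + 20, hi - lo))
        cand <- cand[!(site_key(ch, cand) %in% forbidden)]
        cand <- cand[seq_len(min(snps_per_site, length(cand)))]
        chrom <- c(chrom, rep(ch, length(cand)))
        pos <- c(pos, cand)
        fval <- c(fval, rep(F_by_class[[ind$class[i]]], length(cand)))
        sclass <- c(sclass, rep(ind$class[i], length(cand)))
      }
    }
    dup <- duplicated(site_key(chrom, pos))
    chrom <- chrom[!dup]; pos <- pos[!dup]
    fval <- fval[!dup]; sclass <- sclass[!dup]
    nv <- length(pos)
    ## alleles: anything but a C>T or G>A pair, so background SNPs never
    ## mimic bisulfite artifacts (those are planted by inject_cpg_snps)
    ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
    alt <- vapply(ref, function(r) {
      ok <- setdiff(c("A", "C", "G", "T"), r)
      if (r == "C") ok <- setdiff(ok, "T")
      if (r == "G") ok <- setdiff(ok, "A")
      sample(ok, 1)
    }, character(1))
    anc <- stats::runif(nv, 0.05, 0.95)
    gt <- matrix(NA_character_, nv, nrow(wild),
                 dimnames = list(NULL, wild$sample))
    freqs <- matrix(NA_real_, nv, length(pops),
                    dimnames = list(NULL, names(pops)))
    for (pn in names(pops)) {
      pf <- stats::rbeta(nv, anc * (1 - fval) / fval,
                         (1 - anc) * (1 - fval) / fval)
      pf <- pmin(pmax(pf, 1e-6), 1 - 1e-6)
      freqs[, pn] <- pf
      for (s in pops[[pn]]) {
        nalt <- stats::rbinom(nv, 2, pf)
        gt[, s] <- c("0/0", "0/1", "1/1")[nalt + 1L]
      }
    }
    dp <- matrix(stats::rpois(nv * nrow(wild), dp_mean), nv, nrow(wild))
    gqm <- matrix(gq, nv, nrow(wild))
    V <- variant_table(chrom, pos, ref, alt, gt, dp, gqm,
                       samples = wild$sample)
    ord <- order_sites(chrom, pos)
    attr(V, "snp_truth") <- data.frame(
      chrom = chrom[ord], pos = pos[ord], class = sclass[ord], F = fval[ord],
      anc_freq = anc[ord], freqs[ord, , drop = FALSE],
      stringsAsFactors = FALSE
    )
    V
  })
}

#' Inject C>T / G>A SNPs at CpG sites
#'
#' Plants bisulfite-mimicking SNPs: C>T at the forward C of sampled CpGs and
#' G>A at the guanine (pos+1) of others, with allele frequency `maf` across
#' all genotyped samples. Used to exercise the SNP-correction filter in a
#' closed loop: the injected set is recorded in the `injected` attribute.
#'
#' @param V a [variant_table()] to extend.
#' @param layout a [generate_layout()] result.
#' @param fraction fraction of CpGs to hit (0 returns `V` unchanged).
#' @param maf injected allele frequency (realized sample frequencies vary).
#' @param gq genotype quality written for injected calls.
#' @param dp_mean Poisson depth mean.
#' @param seed RNG seed.
#' @return extended `variant_table` with attribute `injected`
#'   (data.frame `chrom`, `cpg_pos`, `snp_pos`, `type`).
#' @export
inject_cpg_snps <- function(V, layout, fraction = 0.01, maf = 0.3, gq = 60,
                            dp_mean = 20, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_inj <- round(fraction * nrow(layout$cpgs))
  if (n_inj == 0) {
    attr(V, "injected") <- data.frame(chrom = character(0),
                                      cpg_pos = integer(0),
                                      snp_pos = integer(0),
                                      type = character(0),
                                      stringsAsFactors = FALSE)
    return(V)
  }
  existing <- site_key(V$chrom, V$pos)
  withr::with_seed(seed, {
    cand <- sample(nrow(layout$cpgs))
    picked <- integer(0)
    type <- character(0)
    snp_pos <- integer(0)
    for (i in cand) {
      tp <- if (length(picked) %% 2 == 0) "C>T" else "G>A"
      sp <- layout$cpgs$pos[i] + if (tp == "C>T") 0L else 1L
      if (site_key(layout$cpgs$chrom[i], sp) %in% existing) next
      picked <- c(picked, i)
      type <- c(type, tp)
      snp_pos <- c(snp_pos, sp)
      if (length(picked) == n_inj) break
    }
    chrom <- layout$cpgs$chrom[picked]
    nv <- length(picked)
    nsmp <- length(V$samples)
    nalt <- matrix(stats::rbinom(nv * nsmp, 2, maf), nv, nsmp)
    gt <- matrix(c("0/0", "0/1", "1/1")[nalt + 1L], nv, nsmp,
                 dimnames = list(NULL, V$samples))
    dp <- matrix(stats::rpois(nv * nsmp, dp_mean), nv, nsmp)
    gqm <- matrix(gq, nv, nsmp)
    add <- variant_table(chrom, snp_pos,
                         ref = ifelse(type == "C>T", "C", "G"),
                         alt = ifelse(type == "C>T", "T", "A"),
                         gt = gt, dp = dp, gq = gqm, samples = V$samples)
    out <- variant_table(c(V$chrom, add$chrom), c(V$pos, add$pos),
                         c(V$ref, add$ref), c(V$alt, add$alt),
                         rbind(V$gt, add$gt), rbind(V$dp, add$dp),
                         rbind(V$gq, add$gq), samples = V$samples)
    attr(out, "snp_truth") <- attr(V, "snp_truth")
    attr(out, "injected") <- data.frame(
      chrom = chrom, cpg_pos = layout$cpgs$pos[picked], snp_pos = snp_pos,
      type = type, stringsAsFactors = FALSE
    )
    out
  })
}

#' Write / read a complete synthetic scenario to disk
#'
#' Emits one Bismark-style coverage file per sample, the sample sheet, the
#' VCF, the gene models (GFF3), the per-site truth table and optionally the
#' configuration YAML — the on-disk form every reader of the package
#' consumes.
#'
#' @param dir output directory.
#' @param sim a `sim_scenario` from [simulate_methylation()].
#' @param variants optional [variant_table()].
#' @param config optional [analysis_config()].
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(dir, sim, variants = NULL, config = NULL) {
  stopifnot(inherits(sim, "sim_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_coverage_files(sim$matrix, dir)
  write_sample_sheet(sim$sheet, file.path(dir, "samples.tsv"))
  write_results_table(sim$truth, file.path(dir, "truth_sites.tsv"))
  write_gff_genes(sim$layout$genes, file.path(dir, "genes.gff3"))
  utils::write.table(sim$layout$chroms, file.path(dir, "chroms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(variants)) write_vcf_minimal(variants, file.path(dir, "variants.vcf"))
  if (!is.null(config)) write_analysis_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_scenario
#' @return `read_scenario()` returns a list `matrix`, `sheet`, `truth`,
#'   `genes`, `variants` (`NULL` when absent).
#' @export
read_scenario <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  M <- read_coverage_files(file.path(dir, paste0(sheet$sample, ".cov")),
                           sheet$sample)
  vcf <- file.path(dir, "variants.vcf")
  list(
    matrix = M, sheet = sheet,
    truth = read_results_table(file.path(dir, "truth_sites.tsv")),
    genes = read_gff_genes(file.path(dir, "genes.gff3")),
    variants = if (file.exists(vcf)) read_vcf_minimal(vcf) else NULL
  )
}
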