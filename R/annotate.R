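#' Annotate CpG sites with genomic features and nearest TSS
#'
#' Feature precedence across all overlapping genes is
#' promoter > exon > intron > intergenic, where the promoter spans
#' `[TSS - promoter_up, TSS + promoter_down]` on `+` genes (mirrored on
#' `-`), 1-based inclusive. The nearest TSS is chosen by absolute distance
#' with ties broken toward the lexicographically smallest gene id; the
#' signed distance is negative upstream of the TSS (relative to the gene's
#' strand). Permuting the gene input order never changes a call.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param genes a [gene_models()] object.
#' @param promoter_up,promoter_down promoter extent around the TSS, bp.
#' @return data.frame `chrom`, `pos`, `feature`, `nearest_gene`,
#'   `tss_dist` (signed bp, `NA` when the chromosome has no gene),
#'   `containing_gene` (gene span membership, `NA` if none).
#' @export
annotate_features <- function(sites, genes, promoter_up = 1500,
                              promoter_down = 500) {
  stopifnot(inherits(genes, "gene_models"))
  gn <- genes$genes[order(genes$genes$gene_id, method = "radix"), ]
  ex <- genes$exons
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  n <- nrow(sites)
  feature <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  tss_dist <- rep(NA_real_, n)
  containing <- rep(NA_character_, n)
  if (nrow(gn) > 0) {
    prom_start <- ifelse(gn$strand == "+", gn$tss - promoter_up,
                         gn$tss - promoter_down)
    prom_end <- ifelse(gn$strand == "+", gn$tss + promoter_down,
                       gn$tss + promoter_up)
    prom_gr <- GenomicRanges::GRanges(gn$chrom,
                                      IRanges::IRanges(pmax(prom_start, 1), prom_end))
    exon_gr <- GenomicRanges::GRanges(ex$chrom,
                                      IRanges::IRanges(ex$start, ex$end))
    gene_gr <- GenomicRanges::GRanges(gn$chrom,
                                      IRanges::IRanges(gn$start, gn$end))
    in_prom <- IRanges::overlapsAny(site_gr, prom_gr)
    in_exon <- IRanges::overlapsAny(site_gr, exon_gr)
    in_gene <- IRanges::overlapsAny(site_gr, gene_gr)
    feature <- ifelse(in_prom, "promoter",
                      ifelse(in_exon, "exon",
                             ifelse(in_gene, "intron", "intergenic")))
    ## nearest TSS per chromosome; genes pre-sorted by id so the first
    ## minimum wins ties toward the smaller id
    for (ch in unique(sites$chrom)) {
      gi <- which(gn$chrom == ch)
      si <- which(sites$chrom == ch)
      if (!length(gi) || !length(si)) next
      d_abs <- abs(outer(sites$pos[si], gn$tss[gi], "-"))
      best <- max.col(-d_abs, ties.method = "first")
      gbest <- gi[best]
      nearest_gene[si] <- gn$gene_id[gbest]
      tss_dist[si] <- ifelse(gn$strand[gbest] == "+",
                             sites$pos[si] - gn$tss[gbest],
                             gn$tss[gbest] - sites$pos[si])
    }
    ## containing gene: among genes whose span holds the site, the one with
    ## the nearest TSS (ties toward smaller id via the pre-sort)
    hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      dd <- abs(sites$pos[qh] - gn$tss[sh])
      ord <- order(qh, dd, sh)
      first <- !duplicated(qh[ord])
      containing[qh[ord][first]] <- gn$gene_id[sh[ord][first]]
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, feature = feature,
             nearest_gene = nearest_gene, tss_dist = tss_dist,
             containing_gene = containing, stringsAsFactors = FALSE)
}

#' @rdname annotate_features
#' @param chrom,pos a single site.
#' @return `annotate_feature()` returns the single-row version.
#' @export
annotate_feature <- function(chrom, pos, genes, promoter_up = 1500,
                             promoter_down = 500) {
  annotate_features(data.frame(chrom = chrom, pos = pos,
                               stringsAsFactors = FALSE),
                    genes, promoter_up, promoter_down)
}

#' Associate feature calls with genes
#'
#' A site is associated with a gene iff it lies inside the gene span, or is
#' intergenic/promoter-adjacent with `|TSS distance| <= tss_assoc_bp`
#' (boundary inclusive).
#'
#' @param feature_calls output of [annotate_features()].
#' @param tss_assoc_bp maximum TSS distance for association.
#' @return `feature_calls` with a `gene_id` column (`NA` = no association).
#' @export
associate_gene <- function(feature_calls, tss_assoc_bp = 10000) {
  in_gene <- !is.na(feature_calls$containing_gene)
  near <- !is.na(feature_calls$tss_dist) &
    abs(feature_calls$tss_dist) <= tss_assoc_bp
  feature_calls$gene_id <- ifelse(in_gene, feature_calls$containing_gene,
                                  ifelse(near, feature_calls$nearest_gene,
                                         NA_character_))
  feature_calls
}

#' Chi-square goodness-of-fit of DMS features against the background
#'
#' Tests whether DMS are distributed over
#' promoter/exon/intron/intergenic like the full tested CpG set
#' (`chi2 = sum((O-E)^2/E)`, E from background proportions, df = 3).
#' A feature with zero background count is merged into the largest
#' background category (df reduced, logged).
#'
#' @param dms_features character vector of features, or named counts.
#' @param background_features features/counts of all tested CpGs.
#' @return list `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
feature_distribution_test <- function(dms_features, background_features) {
  feats <- c("promoter", "exon", "intron", "intergenic")
  as_counts <- function(x) {
    if (!is.null(names(x)) && is.numeric(x)) {
      out <- stats::setNames(rep(0, length(feats)), feats)
      out[intersect(names(x), feats)] <- x[intersect(names(x), feats)]
      out
    } else {
      table(factor(x, levels = feats))
    }
  }
  obs <- as.numeric(as_counts(dms_features))
  bg <- as.numeric(as_counts(background_features))
  names(obs) <- names(bg) <- feats
  if (any(bg == 0)) {
    zero <- which(bg == 0)
    big <- which.max(bg)
    ec_log("feature_distribution_test: merging %d zero-background category(ies) into '%s'",
           length(zero), feats[big])
    obs[big] <- obs[big] + sum(obs[zero])
    obs <- obs[-zero]
    bg <- bg[-zero]
  }
  expected <- sum(obs) * bg / sum(bg)
  chi2 <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       observed = obs, expected = expected)
}

#' Two-sided Fisher exact test on a gene's 2x3 category table
#'
#' Tests whether the pop-DMS of one gene are distributed over
#' (inducible, stable, inconclusive) like the remaining pop-DMS of the same
#' contrast: exact enumeration of all tables with the observed margins,
#' summing the probabilities of tables no more probable than the observed
#' one (relative tie tolerance 1e-12). Categories empty in both rows are
#' dropped; with a single remaining category p = 1. Should the margin space
#' exceed `max_tables` the p-value is Monte-Carlo estimated with a fixed
#' seed and flagged via an attribute.
#'
#' @param gene_counts length-3 counts (inducible, stable, inconclusive) of
#'   the gene's pop-DMS; total >= 2 for a meaningful test.
#' @param background_counts counts of all other pop-DMS of the contrast.
#' @param max_tables enumeration bound before Monte-Carlo fallback.
#' @param mc_reps,seed Monte-Carlo controls.
#' @return the two-sided p-value.
#' @export
gene_response_fisher <- function(gene_counts, background_counts,
                                 max_tables = 1e7, mc_reps = 1e5, seed = 1) {
  stopifnot(length(gene_counts) == length(background_counts))
  keep <- (gene_counts + background_counts) > 0
  g <- as.numeric(gene_counts[keep])
  b <- as.numeric(background_counts[keep])
  k <- length(g)
  if (k <= 1) return(1)
  r1 <- sum(g)
  cs <- g + b
  N <- sum(cs)
  if (r1 == 0 || r1 == N) return(1)
  logp <- function(x) sum(lchoose(cs, x)) - lchoose(N, r1)
  lp_obs <- logp(g)
  n_tables <- choose(r1 + k - 1, k - 1)
  if (n_tables <= max_tables) {
    tabs <- enumerate_margin_tables(r1, cs)
    lps <- apply(tabs, 1, logp)
    sum(exp(lps[lps <= lp_obs + 1e-12]))
  } else {
    p <- withr::with_seed(seed, {
      draws <- stats::r2dtable(mc_reps, c(r1, N - r1), cs)
      mean(vapply(draws, function(tt) logp(tt[1, ]) <= lp_obs + 1e-12,
                  logical(1)))
    })
    attr(p, "monte_carlo") <- TRUE
    p
  }
}

## all top-row completions (x_1..x_k) with sum r1 and x_j <= column sums
enumerate_margin_tables <- function(r1, cs) {
  k <- length(cs)
  rec <- function(rem, j) {
    if (j == k) {
      if (rem <= cs[k]) return(matrix(rem, 1, 1)) else return(NULL)
    }
    out <- NULL
    for (x in 0:min(rem, cs[j])) {
      sub <- rec(rem - x, j + 1)
      if (!is.null(sub)) out <- rbind(out, cbind(x, sub))
    }
    out
  }
  m <- rec(r1, 1)
  colnames(m) <- NULL
  m
}

#' Per-gene response summary with Fisher exact p-values
#'
#' Builds the per-gene view of the channel classification: for every gene
#' associated with at least `min_sites` pop-DMS, the wild count, the
#' inducible/expected/opposite/stable/inconclusive split, and the
#' [gene_response_fisher()] p-value of the gene's
#' (inducible, stable, inconclusive) row against all remaining pop-DMS of
#' the contrast.
#'
#' @param channels a `channel_table`.
#' @param feature_calls gene-associated calls for the same sites
#'   ([associate_gene()] output).
#' @param min_sites minimum associated pop-DMS per gene.
#' @return data.frame, one row per gene, sorted by descending wild count.
#' @export
gene_response_table <- function(channels, feature_calls, min_sites = 2) {
  key_c <- site_key(channels$chrom, channels$pos)
  key_f <- site_key(feature_calls$chrom, feature_calls$pos)
  gene <- feature_calls$gene_id[match(key_c, key_f)]
  ok <- !is.na(gene) & !is.na(channels$category)
  cats <- c("inducible", "stable", "inconclusive")
  tot <- table(factor(channels$category[ok], levels = cats))
  genes <- names(which(table(gene[ok]) >= min_sites))
  out <- data.frame(gene_id = character(0), n_wild = integer(0),
                    inducible = integer(0), expected = integer(0),
                    opposite = integer(0), stable = integer(0),
                    inconclusive = integer(0), fisher_p = numeric(0),
                    stringsAsFactors = FALSE)
  for (gid in genes) {
    sel <- ok & gene == gid
    cnt <- table(factor(channels$category[sel], levels = cats))
    dirs <- channels$direction[sel & channels$category == "inducible"]
    p <- gene_response_fisher(as.numeric(cnt), as.numeric(tot - cnt))
    out <- rbind(out, data.frame(
      gene_id = gid, n_wild = sum(sel),
      inducible = as.integer(cnt["inducible"]),
      expected = sum(dirs == "expected", na.rm = TRUE),
      opposite = sum(dirs == "opposite", na.rm = TRUE),
      stable = as.integer(cnt["stable"]),
      inconclusive = as.integer(cnt["inconclusive"]),
      fisher_p = as.numeric(p), stringsAsFactors = FALSE
    ))
  }
  out[order(-out$n_wild, out$gene_id), , drop = FALSE]
}
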