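#' Weighted group methylation levels and their difference
#'
#' The weighted mean methylation level of a group at a site pools reads:
#' `100 * sum(methylated) / sum(coverage)` over the group's present samples
#' (so deeply covered individuals weigh more than shallow ones). The
#' reported difference is `level_b - level_a` in percentage points; the
#' caller fixes which group is the reference (`group_a`).
#'
#' @param M a filtered [meth_matrix()].
#' @param sheet a [sample_sheet()].
#' @param group_a,group_b group labels (a = reference, b = target).
#' @return data.frame `chrom`, `pos`, `level_a`, `level_b`, `meth_diff`
#'   (`NA` where a group has no present sample).
#' @export
group_levels <- function(M, sheet, group_a, group_b) {
  stopifnot(inherits(M, "meth_matrix"))
  lv <- function(g) {
    s <- sheet_samples(sheet, g, within = M$samples)
    if (!length(s)) stop("group '", g, "' has no samples in the matrix")
    cov <- rowSums(M$coverage[, s, drop = FALSE], na.rm = TRUE)
    met <- rowSums(M$methylated[, s, drop = FALSE], na.rm = TRUE)
    ifelse(cov > 0, 100 * met / cov, NA_real_)
  }
  la <- lv(group_a)
  lb <- lv(group_b)
  data.frame(chrom = M$sites$chrom, pos = M$sites$pos,
             level_a = la, level_b = lb, meth_diff = lb - la,
             stringsAsFactors = FALSE)
}

#' Per-site binomial logistic-regression likelihood-ratio test
#'
#' Fits `logit(pi_j) = b0 + b1 * group_j (+ family indicators)` to the
#' per-sample (methylated, coverage) pairs by iteratively reweighted least
#' squares (deviance convergence 1e-8, at most 100 iterations) and compares
#' against the model without the group term. The statistic is the deviance
#' difference, chi-square with 1 df. With two groups and no covariate this
#' equals the pooled 2x2 G-statistic.
#'
#' Complete separation drives fitted probabilities to the boundary; the fit
#' still converges to a finite deviance and the site is flagged
#' `"separation"`. A family covariate confounded with group makes the design
#' rank-deficient: flagged `"rank_deficient"`, p absent. Non-convergence is
#' flagged `"nonconverged"`, p absent.
#'
#' @param methylated,coverage integer vectors over samples (present entries
#'   only; coverage >= 1).
#' @param group two-level factor; each level needs >= 2 samples.
#' @param family optional family factor covariate.
#' @param epsilon,maxit IRLS control.
#' @return list `lrt_stat`, `df`, `p`, `flag` (`""` when clean).
#' @export
site_lrt <- function(methylated, coverage, group, family = NULL,
                     epsilon = 1e-8, maxit = 100) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  out_na <- function(flag) list(lrt_stat = NA_real_, df = 1L, p = NA_real_, flag = flag)
  if (min(table(group)) < 2L) return(out_na("insufficient"))
  if (any(coverage < 1)) stop("coverage must be >= 1 for present entries")
  y <- methylated / coverage
  ctrl <- stats::glm.control(epsilon = epsilon, maxit = maxit)
  if (is.null(family)) {
    Xf <- stats::model.matrix(~group)
    Xn <- Xf[, 1L, drop = FALSE]
  } else {
    family <- droplevels(factor(family))
    Xf <- stats::model.matrix(~ group + family)
    Xn <- stats::model.matrix(~family)
  }
  fit_f <- suppressWarnings(stats::glm.fit(Xf, y, weights = coverage,
                                           family = stats::binomial(),
                                           control = ctrl))
  fit_n <- suppressWarnings(stats::glm.fit(Xn, y, weights = coverage,
                                           family = stats::binomial(),
                                           control = ctrl))
  if (!fit_f$converged || !fit_n$converged) return(out_na("nonconverged"))
  if (fit_f$rank < ncol(Xf)) return(out_na("rank_deficient"))
  flag <- ""
  mu <- fit_f$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) flag <- "separation"
  lrt <- max(0, fit_n$deviance - fit_f$deviance)
  list(lrt_stat = lrt, df = 1L,
       p = stats::pchisq(lrt, df = 1L, lower.tail = FALSE), flag = flag)
}

#' Multiple-testing adjustment to q-values
#'
#' Benjamini-Hochberg step-up by default; any `stats::p.adjust` method can
#' be plugged in behind the same interface. Output order matches input;
#' `NA` p-values stay `NA`.
#'
#' @param p_list numeric p-values in `[0, 1]`.
#' @param method adjustment method (see [stats::p.adjust()]).
#' @return q-values in input order.
#' @export
adjust_pvalues <- function(p_list, method = "BH") {
  if (!length(p_list)) return(numeric(0))
  stats::p.adjust(p_list, method = method)
}

#' Call differentially methylated sites
#'
#' DMS iff `q < alpha_q` (strict) and `|meth_diff| >= min_diff_pct`
#' (inclusive).
#'
#' @param results data.frame carrying `q` and `meth_diff`.
#' @param alpha_q,min_diff_pct thresholds.
#' @return logical vector, `FALSE` where q is absent.
#' @export
call_dms <- function(results, alpha_q = 0.0125, min_diff_pct = 15) {
  !is.na(results$q) & results$q < alpha_q &
    !is.na(results$meth_diff) & abs(results$meth_diff) >= min_diff_pct
}

#' Pairwise differential-methylation comparison between two groups
#'
#' Orchestrates [group_levels()], [site_lrt()] per site (with the family
#' covariate attached automatically iff both groups are experimental),
#' [adjust_pvalues()] and [call_dms()]. Deterministic given its inputs.
#'
#' @param M a filtered [meth_matrix()].
#' @param sheet a [sample_sheet()].
#' @param group_a reference group; `group_b` target group
#'   (`meth_diff = b - a`).
#' @param group_b target group.
#' @param config an [analysis_config()].
#' @return data.frame of class `diffmeth_table`: `chrom`, `pos`, `level_a`,
#'   `level_b`, `meth_diff`, `lrt_stat`, `df`, `p`, `q`, `dms`, `flag`;
#'   attributes `group_a`, `group_b`, `covariate`.
#' @export
compare_groups <- function(M, sheet, group_a, group_b,
                           config = analysis_config()) {
  sa <- sheet_samples(sheet, group_a, within = M$samples)
  sb <- sheet_samples(sheet, group_b, within = M$samples)
  if (length(sa) < 2 || length(sb) < 2) {
    stop("compare_groups: both groups need >= 2 samples in the matrix")
  }
  use_family <- all(sheet$cohort[sheet$group %in% c(group_a, group_b)] ==
                      "experimental")
  lev <- group_levels(M, sheet, group_a, group_b)
  sel <- c(sa, sb)
  cov <- M$coverage[, sel, drop = FALSE]
  met <- M$methylated[, sel, drop = FALSE]
  grp <- factor(rep(c("a", "b"), c(length(sa), length(sb))), levels = c("a", "b"))
  fam <- if (use_family) factor(sheet$family[match(sel, sheet$sample)]) else NULL
  n <- nrow(cov)
  lrt <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    pres <- which(!is.na(cov[i, ]))
    gi <- grp[pres]
    if (sum(gi == "a") < 2L || sum(gi == "b") < 2L) {
      flag[i] <- "insufficient"
      next
    }
    r <- site_lrt(met[i, pres], cov[i, pres], gi,
                  family = if (!is.null(fam)) fam[pres])
    lrt[i] <- r$lrt_stat
    p[i] <- r$p
    flag[i] <- r$flag
  }
  out <- data.frame(
    chrom = lev$chrom, pos = lev$pos,
    level_a = lev$level_a, level_b = lev$level_b, meth_diff = lev$meth_diff,
    lrt_stat = lrt, df = 1L, p = p, q = adjust_pvalues(p),
    flag = flag, stringsAsFactors = FALSE
  )
  out$dms <- call_dms(out, config$alpha_q, config$min_diff_pct)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "covariate") <- if (use_family) "family" else "none"
  class(out) <- c("diffmeth_table", "data.frame")
  out
}
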