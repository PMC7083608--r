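#' Classify a population DMS as stable, inducible or inconclusive
#'
#' The core partition: a population-differential CpG (pop-DMS) is compared
#' against the two acclimation contrasts of the experiment (control vs
#' within-generation group, control vs transgenerational group).
#' *Inducible*: at least one contrast is itself a DMS (`q < alpha_q` and
#' `|diff| >= min_diff_pct`). *Stable*: both contrasts are non-significant
#' (`q >= alpha_q`). *Inconclusive*: some contrast is significant but none
#' reaches the effect-size threshold. Precedence is
#' inducible > inconclusive > stable. Any missing q yields `NA` (site not
#' classifiable).
#'
#' @param q_within,diff_within q-value and methylation difference
#'   (percentage points) of the control-vs-within contrast; vectorized.
#' @param q_trans,diff_trans same for the control-vs-transgenerational
#'   contrast.
#' @param alpha_q,min_diff_pct thresholds.
#' @return data.frame `category` (`stable`/`inducible`/`inconclusive`/`NA`)
#'   and `induced_by` (`""`, `"within"`, `"trans"`, `"within+trans"`).
#' @export
classify_channel <- function(q_within, diff_within, q_trans, diff_trans,
                             alpha_q = 0.0125, min_diff_pct = 15) {
  ind_w <- !is.na(q_within) & q_within < alpha_q &
    !is.na(diff_within) & abs(diff_within) >= min_diff_pct
  ind_t <- !is.na(q_trans) & q_trans < alpha_q &
    !is.na(diff_trans) & abs(diff_trans) >= min_diff_pct
  sig_any <- (!is.na(q_within) & q_within < alpha_q) |
    (!is.na(q_trans) & q_trans < alpha_q)
  category <- ifelse(ind_w | ind_t, "inducible",
                     ifelse(sig_any, "inconclusive", "stable"))
  category[is.na(q_within) | is.na(q_trans)] <- NA_character_
  induced_by <- ifelse(ind_w & ind_t, "within+trans",
                       ifelse(ind_w, "within", ifelse(ind_t, "trans", "")))
  induced_by[is.na(category)] <- NA_character_
  data.frame(category = category, induced_by = induced_by,
             stringsAsFactors = FALSE)
}

#' Match the induced direction against the wild population difference
#'
#' An inducible site moved in the *expected* direction when the sign of the
#' experimental change (treatment - control) equals the sign of the wild
#' difference (target population - reference population): the experimental
#' fish became more similar to the wild population at the corresponding
#' salinity. Opposite signs reduce that similarity. When both contrasts
#' induce and disagree, the transgenerational contrast wins and the conflict
#' is flagged. A zero wild difference cannot be matched
#' (`"not-applicable"`).
#'
#' @param wild_diff wild target-minus-reference difference (pp); vectorized.
#' @param exp_diff_within,exp_diff_trans experimental differences (pp).
#' @param induced_by which contrasts induced (from [classify_channel()]).
#' @return data.frame `direction` (`expected`/`opposite`/`not-applicable`)
#'   and `conflict` (logical).
#' @export
classify_direction <- function(wild_diff, exp_diff_within, exp_diff_trans,
                               induced_by) {
  n <- length(wild_diff)
  direction <- rep(NA_character_, n)
  conflict <- rep(FALSE, n)
  lab <- function(e, w) ifelse(sign(e) == sign(w), "expected", "opposite")
  for (i in seq_len(n)) {
    ib <- induced_by[i]
    if (is.na(ib) || ib == "") next
    if (wild_diff[i] == 0) {
      direction[i] <- "not-applicable"
      next
    }
    has_w <- ib %in% c("within", "within+trans")
    has_t <- ib %in% c("trans", "within+trans")
    dw <- if (has_w) lab(exp_diff_within[i], wild_diff[i]) else NA
    dt <- if (has_t) lab(exp_diff_trans[i], wild_diff[i]) else NA
    if (has_w && has_t) {
      direction[i] <- dt
      conflict[i] <- !identical(dw, dt)
    } else {
      direction[i] <- if (has_t) dt else dw
    }
  }
  data.frame(direction = direction, conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Similarity of an experimental methylation shift to the wild difference
#'
#' `delta.meth.diff = 100 - (meth.diff.wild - meth.diff.exp)`, computed
#' after orienting each site so the wild difference is non-negative (both
#' signs flipped together when `wild_diff < 0`; without the orientation the
#' formula would reward overshooting in one sign direction only). 100 means
#' the experimental change exactly reproduces the wild difference; smaller
#' values mean the experiment fell short; values above 100 are overshoots.
#'
#' @param wild_diff,exp_diff differences in percentage points; vectorized.
#' @return numeric delta.meth.diff values (target 100).
#' @export
delta_meth_diff <- function(wild_diff, exp_diff) {
  s <- ifelse(wild_diff < 0, -1, 1)
  100 - (s * wild_diff - s * exp_diff)
}

#' Build the channel table for a set of population DMS
#'
#' Joins the wild comparison with the two experimental contrasts, classifies
#' each pop-DMS ([classify_channel()]), assigns the induced direction
#' ([classify_direction()]), the methylation direction (hypo iff the raw
#' induced change, treatment minus control, is negative; taking the transgenerational
#' contrast when it induces, otherwise the within-generation one), and both
#' delta.meth.diff values.
#'
#' @param wild_tab `diffmeth_table` of the wild contrast
#'   (reference vs target population).
#' @param within_tab,trans_tab `diffmeth_table`s of control-vs-within and
#'   control-vs-transgenerational contrasts.
#' @param config an [analysis_config()].
#' @param popdms optional data.frame (`chrom`, `pos`) restricting the set;
#'   defaults to the DMS rows of `wild_tab`.
#' @return data.frame of class `channel_table`, one row per pop-DMS.
#' @export
classify_channels <- function(wild_tab, within_tab, trans_tab,
                              config = analysis_config(), popdms = NULL) {
  if (is.null(popdms)) popdms <- wild_tab[wild_tab$dms, c("chrom", "pos")]
  keys <- site_key(popdms$chrom, popdms$pos)
  iw <- match(keys, site_key(wild_tab$chrom, wild_tab$pos))
  ii <- match(keys, site_key(within_tab$chrom, within_tab$pos))
  it <- match(keys, site_key(trans_tab$chrom, trans_tab$pos))
  n_missing <- sum(is.na(ii) | is.na(it))
  if (n_missing > 0) {
    ec_log("classify_channels: %d pop-DMS missing from an experimental contrast", n_missing)
  }
  wild_diff <- wild_tab$meth_diff[iw]
  dw <- within_tab$meth_diff[ii]
  dt <- trans_tab$meth_diff[it]
  qw <- within_tab$q[ii]
  qt <- trans_tab$q[it]
  cls <- classify_channel(qw, dw, qt, dt, config$alpha_q, config$min_diff_pct)
  dir <- classify_direction(wild_diff, dw, dt, cls$induced_by)
  ## hypo/hyper is the raw sign of the induced change (treatment - control),
  ## NOT the oriented one: after orientation the sign would coincide with the
  ## expected/opposite label and the direction x acclimation design would be
  ## confounded
  use_trans <- !is.na(cls$induced_by) &
    cls$induced_by %in% c("trans", "within+trans")
  exp_used <- ifelse(use_trans, dt, dw)
  meth_direction <- ifelse(cls$category == "inducible",
                           ifelse(exp_used < 0, "hypo", "hyper"),
                           NA_character_)
  out <- data.frame(
    chrom = popdms$chrom, pos = popdms$pos,
    wild_diff = wild_diff,
    exp_diff_within = dw, exp_diff_trans = dt,
    q_within = qw, q_trans = qt,
    category = cls$category, induced_by = cls$induced_by,
    direction = dir$direction, conflict = dir$conflict,
    meth_direction = meth_direction,
    oriented = wild_diff < 0,
    delta_meth_diff_within = delta_meth_diff(wild_diff, dw),
    delta_meth_diff_trans = delta_meth_diff(wild_diff, dt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("channel_table", "data.frame")
  out
}

#' Two-way ANOVA of delta.meth.diff on direction and acclimation
#'
#' Fixed-effects least-squares ANOVA on the 2x2 design (methylation
#' direction hypo/hyper x acclimation within/trans), with Type-II sums of
#' squares for unbalanced cells. Reports the acclimation main effect and
#' the direction-by-acclimation interaction. With an empty cell the
#' interaction is not estimable: the main effect comes from the additive
#' model and the result is flagged.
#'
#' @param values per-observation delta.meth.diff.
#' @param meth_direction factor `hypo`/`hyper`.
#' @param acclimation factor `within`/`trans`.
#' @return list `F_main`, `p_main`, `F_interaction`, `p_interaction`,
#'   `df_resid`, `flag`.
#' @export
acclimation_anova <- function(values, meth_direction, acclimation) {
  d <- data.frame(y = values,
                  direction = droplevels(factor(meth_direction)),
                  acclim = droplevels(factor(acclimation)))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(d$direction) < 2 || nlevels(d$acclim) < 2) {
    stop("acclimation_anova: both factors need two observed levels")
  }
  cells <- table(d$direction, d$acclim)
  if (any(cells == 0)) {
    fit <- stats::lm(y ~ direction + acclim, data = d)
    a2 <- car::Anova(fit, type = 2)
    return(list(F_main = a2["acclim", "F value"],
                p_main = a2["acclim", "Pr(>F)"],
                F_interaction = NA_real_, p_interaction = NA_real_,
                df_resid = stats::df.residual(fit), flag = "empty_cell"))
  }
  fit <- stats::lm(y ~ direction * acclim, data = d)
  a2 <- car::Anova(fit, type = 2)
  list(F_main = a2["acclim", "F value"],
       p_main = a2["acclim", "Pr(>F)"],
       F_interaction = a2["direction:acclim", "F value"],
       p_interaction = a2["direction:acclim", "Pr(>F)"],
       df_resid = stats::df.residual(fit), flag = "")
}

#' Are pop-DMS enriched for inducible sites?
#'
#' Draws `reps` random site sets of the pop-DMS size (without replacement)
#' from all classifiable CpG sites, averages their
#' stable/inducible/inconclusive counts as the expected composition, and
#' compares the observed pop-DMS counts with a chi-square statistic
#' `sum((obs-exp)^2/exp)`, df = 2.
#'
#' @param universe_categories category per classifiable CpG of the complete
#'   dataset (`NA`s are dropped with a log message).
#' @param observed_counts named or ordered counts
#'   (inducible, stable, inconclusive) of the pop-DMS.
#' @param reps number of replicates.
#' @param seed RNG seed (bit-reproducible).
#' @param n_popdms set size; defaults to `sum(observed_counts)`.
#' @return list `observed`, `expected`, `chi2`, `df`, `p`, `reps`.
#' @export
enrichment_randomization <- function(universe_categories, observed_counts,
                                     reps = 1000, seed = 1, n_popdms = NULL) {
  cats <- c("inducible", "stable", "inconclusive")
  u <- factor(universe_categories, levels = cats)
  n_na <- sum(is.na(u))
  if (n_na > 0) ec_log("enrichment_randomization: %d unclassifiable site(s) dropped", n_na)
  code <- as.integer(u[!is.na(u)])
  obs <- if (!is.null(names(observed_counts))) {
    as.numeric(observed_counts[cats])
  } else {
    as.numeric(observed_counts)
  }
  stopifnot(length(obs) == 3L, !anyNA(obs))
  n <- if (is.null(n_popdms)) sum(obs) else n_popdms
  if (n > length(code)) stop("n_popdms exceeds the number of classifiable sites")
  counts <- matrix(0, reps, 3L)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      counts[r, ] <- tabulate(code[sample.int(length(code), n)], nbins = 3L)
    }
  })
  expected <- colMeans(counts)
  names(expected) <- cats
  names(obs) <- cats
  nz <- expected > 0
  if (any(!nz & obs > 0)) {
    chi2 <- Inf
  } else {
    chi2 <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  }
  list(observed = obs, expected = expected, chi2 = chi2, df = 2L,
       p = stats::pchisq(chi2, df = 2L, lower.tail = FALSE), reps = reps)
}

#' Hepatosomatic index
#'
#' `HSI = liver weight / total weight * 100`, a proxy for energy reserves
#' (liver glycogen). Weights must be positive and in the same unit.
#'
#' @param liver_weight,total_weight positive weights; vectorized.
#' @return HSI values.
#' @export
hepatosomatic_index <- function(liver_weight, total_weight) {
  if (any(!is.finite(liver_weight)) || any(!is.finite(total_weight)) ||
      any(liver_weight <= 0) || any(total_weight <= 0)) {
    stop("hepatosomatic_index: weights must be positive")
  }
  liver_weight / total_weight * 100
}
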