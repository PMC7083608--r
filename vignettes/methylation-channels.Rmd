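---
title: "Partitioning differential DNA methylation into stable and inducible channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning differential DNA methylation into stable and inducible channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the design

Populations adapted to different environments frequently differ in CpG
methylation. Such population-differential methylated sites (pop-DMS) can
belong to two information channels with very different evolutionary
interpretations: *stable* marks, which do not respond to the environmental
variable under study and are candidates for selection on epimutations or
for passengers of genetic divergence, and *inducible* marks, which respond
to the environment and can implement (transgenerational) plasticity.

`epichannels` operationalizes the distinction with a space-for-time design:
wild populations from the two ends of an environmental gradient define the
target methylation states, and a laboratory experiment exposes offspring of
the mid-gradient population to the foreign condition for one
(within-generation) or two (transgenerational) generations. A pop-DMS that
does not move in the experiment is classified *stable*; one that becomes
differentially methylated relative to the control group is *inducible*; a
site with a significant but sub-threshold shift is *inconclusive*.

## The statistical model

**Per-site test.** Methylation counts are binomial at the read level: for
sample $j$ with coverage $n_j$ and methylated count $m_j$,
$m_j \sim \mathrm{Bin}(n_j, \pi_j)$ with
$\mathrm{logit}(\pi_j) = \beta_0 + \beta_1\,\mathrm{group}_j
(+ \gamma_{f(j)})$. The family terms $\gamma_f$ are included exactly when
both groups are experimental: the split-clutch breeding design places every
family in every treatment group, so family is a legitimate covariate there,
while wild fish have no family structure. The test statistic is the
deviance difference between the null and full fits (IRLS, deviance
convergence $10^{-8}$, at most 100 iterations), compared to $\chi^2_1$.
With two groups and no covariate this statistic *is* the pooled 2x2
G-statistic, which the test suite verifies to $10^{-6}$ on 1000 random
instances against an independently coded oracle.

The model deliberately ignores extra-binomial variation (the convention of
the tooling this pipeline follows). The synthetic generator, by contrast,
*does* produce beta-binomial counts (default intra-sample correlation
$\rho = 0.01$), so the calibration of the test can be assessed honestly:
under a pure binomial null the raw $P(p < 0.05)$ sits at the nominal level
(asserted at $0.05 \pm 0.01$ on 5000 null sites), while overdispersion
inflates the statistic by roughly the variance-inflation factor
$1 + (\bar n - 1)\rho$ — about 1.3 at coverage 30 — which roughly doubles
the raw type-I rate. The pipeline's operational decisions are protected
from this inflation by the BH step (which faces a near-null p distribution
only under the binomial model) and, much more strongly, by the 15-pp
effect-size threshold: in the same overdispersed null run the suite's
settings yield zero false DMS.

**Multiple testing.** p-values are converted to q-values with
Benjamini–Hochberg. Sliding-linear-model (SLIM) q-values are sometimes used for this kind of
data, but the estimator's $\pi_0$ step is not defined tightly enough for a
faithful re-implementation, so BH — conservative under the complete null — is
the default, and `adjust_pvalues()` exposes the `method` argument so any
`stats::p.adjust` method (or a future SLIM implementation) can be swapped
in without touching callers. The significance threshold $q < 0.0125$ is a
Bonferroni-style correction of 0.05 for the four group comparisons each
dataset takes part in, applied to q as in the original design.

**DMS definition.** $q < 0.0125$ (strict) *and* $|\Delta| \ge 15$ pp
(inclusive), where $\Delta$ is the difference of *read-weighted* group
methylation levels, $100\sum_j m_j / \sum_j n_j$ per group — deeply covered
individuals carry more weight, matching the binomial likelihood.

## The filter chain

Applied in this fixed order:

1. **Minimum coverage** 10 reads (inclusive); lower entries become absent.
   Absence is always explicit (`NA`), never coverage 0.
2. **Percentile cap** at the 99.9th empirical percentile (type-7 linear
   interpolation), strictly above; a PCR-duplicate guard. The scope is
   per sample by default (`high_cov_scope = "global"` pools), since
   coverage distributions are library-specific.
3. **SNP correction**: any CpG whose C carries a polymorphic C>T, or whose
   G (position +1) carries a G>A, among variants with mean GQ >= 20 and
   sample MAF >= 0.005, is removed entirely — such SNPs mimic bisulfite
   conversion. Variants lacking GQ never trigger removal (their quality
   cannot be certified).
4. **Coverage normalization** between samples: sample $j$ with median
   coverage $m_j$ is scaled by $s_j = \mathrm{median}(m)/m_j$ (target
   `"max"` available), with half-away-from-zero rounding, present
   coverages floored at 1, and methylated counts clamped to
   $[0, n']$ — the methylation fraction moves by at most $1/n'$.
5. **Presence**: a site must be observed in >= 9 individuals of *every*
   group.
6. **Sex chromosome** removal (label configurable, default `chr19`), since
   sex-specific methylation concentrates there.
7. **Blacklist**: DMS called between the wild reference population and the
   experimental control group are treated as laboratory artifacts and
   subtracted from every pop-DMS set.

Two numerical caveats are intrinsic rather than bugs: the percentile cap is
not strictly idempotent (a second application re-estimates a lower
threshold from the survivors), and integer rounding means normalization is
idempotent only up to one unit of median coverage. The chain applies each
exactly once; the remaining filters are idempotent and tested as such.

## Channel classification and delta.meth.diff

For each pop-DMS with results in both acclimation contrasts:

* **inducible** iff at least one contrast is itself a DMS
  ($q < 0.0125$ and $|\Delta| \ge 15$);
* **stable** iff both contrasts have $q \ge 0.0125$;
* **inconclusive** otherwise (significant q, sub-threshold effect).

The precedence inducible > inconclusive > stable resolves mixed states in
favour of the "at least one acclimation group" reading. Sites missing from
a contrast are left unclassified and logged, never silently dropped into a
category.

**Direction.** An inducible site moved in the *expected* direction when
$\mathrm{sign}(\Delta_{exp}) = \mathrm{sign}(\Delta_{wild})$, with
$\Delta_{wild}$ = target wild population minus reference. When both
contrasts induce and disagree, the transgenerational contrast decides and
the conflict is flagged; $\Delta_{wild} = 0$ is `not-applicable`.

**Similarity.** $\delta_{meth} = 100 - (\Delta_{wild} - \Delta_{exp})$,
evaluated after flipping both signs so $\Delta_{wild} \ge 0$. Without the
orientation the formula would reward overshoots for positively oriented
sites and punish them for negative ones; the flip makes 100 mean "the
experiment reproduced the wild difference exactly" for every site, and the
orientation is recorded per site. Values above 100 (overshoot) are legal.

**Hypo/hyper.** The methylation direction of an inducible site is the *raw*
sign of the induced change (treatment minus control), taking the
transgenerational contrast when it induces. This is a deliberate choice
over an "oriented" sign: after orientation the sign coincides exactly with
the expected/opposite label, which would make the direction x acclimation
ANOVA rank-deficient within a direction class — the raw sign is also what
the hypo/hypermethylation split means biologically.

**Enrichment.** Are pop-DMS enriched for inducible sites relative to
arbitrary CpGs? `enrichment_randomization()` draws 1000 random site sets of
the pop-DMS size from all classifiable sites, averages their category
counts as the expectation, and compares the observed counts with
$\chi^2_2 = \sum (O-E)^2/E$. The test suite checks that its p-value is
approximately uniform when the "pop-DMS" really are a random subset.

**Acclimation ANOVA.** $\delta_{meth} \sim$ direction $\times$ acclimation
(within/trans), fixed effects, Type-II sums of squares for the unbalanced
cells that real classifications produce (`car::Anova`; the balanced case is
verified against a hand-computed decomposition). With an empty cell the
interaction is not estimable: the main effect is reported from the
additive model and the result flagged.

## Windowed FST and the delta.mean.FST randomization

Per biallelic SNP, the two-population Weir–Cockerham
$\hat\theta = a/(a+b+c)$ is computed from sample sizes, allele frequencies
and observed heterozygosities; negative estimates are retained (they are
part of the estimator's sampling distribution, and truncation would bias
window means upward). Windows are $\pm 5$ kb around each inducible
pop-DMS; genotypes with depth < 5 (or unknown depth) count as missing, and
a SNP with more than 60% missing genotypes *jointly across both
populations* is dropped (the joint reading is the convention of the
windowed tooling; a per-population reading would keep more marginal SNPs).
The window summary is the arithmetic mean of per-SNP estimates — the
`MEAN_FST` convention — with the ratio-of-sums weighted estimate reported
alongside.

`delta_mean_fst_test()` compares expected vs opposite window means:
$\delta = \bar F_{exp} - \bar F_{opp}$, null distribution by reassigning
the pooled values to the two group sizes (label permutation, 10000
replicates; a with-replacement bootstrap sits behind a flag), one-tailed
$p = \#\{\delta^* < \delta_{obs}\}/n$. The raw count ratio is reported
deliberately — it can be exactly 0 — and the $(c+1)/(n+1)$ correction is
available via `fst_p_plus_one`. On 10 or fewer pooled values the
permutation p is checked against exhaustive enumeration of all
assignments.

## Annotation and the per-gene Fisher test

Features follow the precedence promoter > exon > intron > intergenic
across *all* overlapping genes, with the promoter spanning 1500 bp upstream
to 500 bp downstream of the TSS (strand-mirrored, 1-based inclusive). The
nearest TSS is chosen by absolute distance with ties broken toward the
lexicographically smallest gene id, making calls independent of gene input
order. A site is gene-associated iff it lies inside a gene span or its
nearest TSS is within 10 kb (inclusive). The DMS-vs-background feature
distribution is tested by chi-square goodness-of-fit (df 3; a feature with
zero background count is merged into the largest category with df
reduced).

For genes carrying several pop-DMS, the 2x3 table (gene row vs all
remaining pop-DMS) over (inducible, stable, inconclusive) is tested by
Fisher's exact test implemented as exhaustive enumeration of the
fixed-margin space, summing probabilities no larger than the observed
table's (relative tie tolerance $10^{-12}$). The gene-vs-remaining
construction is the most direct reading of a "correlated response"
hypothesis; other defensible contingency constructions exist, so per-gene
p-values should be read as documented output of this construction. Enumerated probabilities sum to 1 ($10^{-9}$), and
2x2 reductions reproduce the classical two-sided hypergeometric p; a
seeded Monte-Carlo fallback exists for margin spaces beyond $10^7$ tables
(unreachable with realistic gene totals).

## The synthetic generator

The generator is the package's study system, not a tuning knob. Defaults:

* **Design**: wild groups n = 15/16/15 (low/reference/high condition);
  five experimental groups of 12 (control, within- and transgenerational
  acclimation to each foreign condition) sharing 6 split-clutch families.
* **Baselines**: $\pi_0 \sim 0.5\,\mathrm{Beta}(0.5, 8) +
  0.5\,\mathrm{Beta}(8, 0.5)$ — the bimodal (mostly un- or fully
  methylated) profile of vertebrate CpGs.
* **Planted truth**: 100 population effects of $\pm 30$ pp (random sign)
  on the low-condition contrast: 40 inducible-expected
  ($\Delta_{within} = 0.6\,\Delta_{wild}$, $\Delta_{trans} =
  \Delta_{wild}$ — the attenuation factor 0.6 makes transgenerational
  groups sit closer to the wild state, the accentuation the design is
  meant to detect), 20 inducible-opposite (same magnitudes, opposite
  sign), 20 inconclusive (10 pp induced change: significant but below the
  15-pp threshold at the default power), 20 purely stable. Planted sites
  draw $\pi_0$ from (0.35, 0.65) so $\pm 30$ pp fits inside the
  probability scale; group means are clipped to [0.01, 0.99] with clipping
  logged. The high-condition groups carry no planted effects by default:
  the default scenario is a single-contrast study, and the second contrast
  exists for design realism (presence filtering across all eight groups)
  and pipeline completeness.
* **Counts**: coverage $\sim$ NegBin(mean 30, size 5) floored at 1;
  methylated counts beta-binomial with $\rho = 0.01$ — deliberately
  harsher than the binomial test assumes. Family effects are
  per-site-per-family Normal(0, 0.3) shifts on the logit scale, shared
  across treatment groups as a split-clutch design implies.
* **Genotypes**: Balding–Nichols — ancestral frequency uniform on
  (0.05, 0.95), population frequencies
  $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$, Hardy–Weinberg genotypes,
  depth $\sim$ Poisson(20), GQ 60. Background SNPs (F = 0.10, matching a
  moderately structured pair of populations) avoid CpG positions; every
  planted inducible site is guaranteed 10 SNPs within its window, drawn
  with F = 0.02 near expected sites and F = 0.25 near opposite sites —
  encoding the hypothesis that opposite responses occur on differentiated
  genomic backgrounds, so the FST machinery can be validated against
  truth. `inject_cpg_snps()` plants C>T/G>A variants directly on CpGs to
  close the loop on the SNP-correction filter.

All generators are pure functions of (parameters, seed); per-stage seeds
derive from one master seed through fixed offsets, so adding a stage never
perturbs another.

**What passing tests do and do not show.** The generator emulates the
statistical structure the analysis assumes (binomial/beta-binomial counts,
bimodal baselines, family structure, Hardy–Weinberg genotypes with
beta-distributed frequencies). It does not emulate alignment artifacts,
bisulfite conversion failure, methylation–genotype linkage on haplotypes,
selection during the experiment, or correlated methylation of neighbouring
CpGs. Recovery and calibration on synthetic data therefore validate the
*computations*, not the upstream data quality of a real RRBS study.

## Problem sizes and reproducibility

The default validation scenario uses 5000 CpGs on three chromosomes
(1 Mb autosomes, a quarter-length sex chromosome), 2000 background SNPs
and the full eight-group design — large enough for stable rates, small
enough that the complete suite (around 700 assertions, including two
full scenario analyses) runs in a few minutes on one CPU. The
acceptance script `scripts/acceptance.R` re-runs the default scenario from
a command-line seed and writes every headline quantity as JSON; identical
seeds give byte-identical artifacts, which the pipeline records as md5
checksums in per-stage provenance files.

## Known limitations

* SLIM q-values are not implemented; BH is the default adjuster (interface
  accepts alternatives).
* One categorical covariate (family) only; no DMR-level calling, no
  beta-binomial or shrinkage tests.
* Two-population FST only; no haplotype statistics or LD pruning.
* Destranding of coverage files requires the forward-C position set, since
  the format itself carries no strand.
* The per-gene Fisher construction (gene vs remaining pop-DMS) is one
  defensible reading of the correlated-response hypothesis; others exist.
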