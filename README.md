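# epichannels

Wild populations that have adapted to different environments often differ
in DNA methylation at thousands of CpG sites. Two very different mechanisms
can produce such population-differential methylated sites (pop-DMS):
**stable** epigenetic marks that arise as random epimutations and are then
shaped by selection (or track underlying genetic divergence), and
**inducible** marks that respond directly to the environment and can carry
information across generations (transgenerational plasticity). Telling the
two channels apart requires combining a field survey with a
multi-generation acclimation experiment.

`epichannels` implements that analysis as a tested, reusable R pipeline for
reduced-representation bisulfite sequencing (RRBS) count data plus
whole-genome SNP genotypes. It is aimed at molecular ecologists and
evolutionary (epi)geneticists who have per-CpG methylation counts for wild
populations and for laboratory treatment groups and want to partition
pop-DMS into stable, inducible and inconclusive classes — and to ask
whether induced changes move *toward* the wild pattern and how that relates
to local genetic differentiation.

## What it computes

* **DMS calling.** Per CpG site, a binomial logistic regression
  `logit(pi_j) = b0 + b1 * group_j (+ family_f)` is fit to per-sample
  (methylated, coverage) pairs; the likelihood-ratio statistic
  (null deviance minus full deviance, chi-square with 1 df) is converted to
  Benjamini–Hochberg q-values. A site is a DMS when `q < 0.0125` and the
  read-weighted group methylation difference is at least 15 percentage
  points. The full filter chain (coverage >= 10, 99.9th-percentile cap,
  C>T/G>A SNP exclusion, between-sample coverage normalization, presence in
  >= 9 individuals per group, sex-chromosome removal, lab-artifact
  blacklist) is applied first.
* **Channel classification.** Each pop-DMS is compared against the two
  acclimation contrasts (control vs within-generation group, control vs
  transgenerational group): *inducible* if at least one contrast is itself
  a DMS, *stable* if both are non-significant, *inconclusive* otherwise.
  Inducible sites are labelled *expected* when the induced change has the
  sign of the wild difference, *opposite* otherwise, and their similarity
  to the wild state is quantified as
  `delta.meth.diff = 100 - (meth.diff.wild - meth.diff.exp)` (100 = the
  experiment exactly reproduces the wild difference). A randomization test
  (random CpG sets of the pop-DMS size, chi-square on the category counts)
  asks whether pop-DMS are enriched for inducible sites, and a
  direction-by-acclimation ANOVA asks whether two generations of
  acclimation track the wild state more closely than one.
* **Genetic differentiation.** Per-SNP Weir–Cockerham theta between the two
  wild populations, averaged in +/- 5 kb windows around each inducible
  pop-DMS (genotypes with depth < 5 set missing, SNPs with > 60% missing
  dropped), and the one-tailed randomization test on
  `delta.mean.FST = mean FST(expected) - mean FST(opposite)`.
* **Annotation.** Promoter (TSS -1500/+500) / exon / intron / intergenic
  calls with a chi-square goodness-of-fit against the tested background,
  gene association (inside the gene or TSS within 10 kb), and a per-gene
  2x3 Fisher exact test (exact enumeration) for correlated responses of
  pop-DMS on the same gene.
* **Synthetic scenarios.** A generator for methylomes (bimodal baselines,
  beta-binomial counts, split-clutch family effects, planted wild and
  induced effects) and Balding–Nichols genotypes with class-specific
  differentiation, so the whole pipeline is validated end to end against
  known ground truth.

## Worked example

Generate a small synthetic study (800 CpGs; three wild populations and five
treatment groups; 100 planted population effects of +/-30 pp, 60 of them
inducible) and run the full analysis for the low-salinity contrast:

```r
library(epichannels)
res <- run_scenario(seed = 7,
                    layout_args = list(n_cpg = 800, n_genes = 30,
                                       chrom_len = 4e5),
                    contrasts = "decrease")
ct <- res$contrasts$decrease
nrow(ct$popdms)                      # pop-DMS after blacklist: 96
table(ct$channels$category)
#> inconclusive    inducible       stable
#>            3           63           30
table(ct$channels$direction[ct$channels$category == "inducible"])
#> expected opposite
#>       43       20
ct$enrichment$chi2                   # 384.9 (df 2), p = 2.6e-84
ct$delta_fst$delta                   # -0.0468, one-tailed p = 0
scenario_metrics(res, "decrease")
#> recovery 96%, category accuracy 100%, direction accuracy 100%
```

Reading: of the 96 recovered pop-DMS, 63 responded to the experimental
treatment (inducible), 30 did not (stable), 3 were significant but below
the 15-pp effect threshold. Two-thirds of the inducible sites moved toward
the wild pattern (expected), and windows around opposite-direction sites
are more genetically differentiated (negative delta.mean.FST, one-tailed
p reported as the raw count/n ratio, here 0/10000) — exactly the structure
the generator planted.

Real data enter through `read_coverage_files()` (Bismark coverage),
`read_sample_sheet()`, `read_vcf_minimal()` and `read_gff_genes()`; the
staged, file-based `run_pipeline()` writes every intermediate table with
provenance checksums.

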