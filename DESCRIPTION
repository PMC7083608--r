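Package: epichannels
Title: Stable and Inducible DNA Methylation Channels from Population
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions population-differential DNA methylation (RRBS) into
    stable (selection-candidate) and inducible (plasticity-candidate)
    epigenetic channels. Provides readers for Bismark-style coverage files,
    sample sheets, VCF and GFF3; the site/sample filter chain used for
    reduced-representation bisulfite data (minimum and percentile coverage,
    C-to-T/G-to-A SNP exclusion, between-sample coverage normalization,
    per-group presence, sex-chromosome removal); per-CpG differential
    methylation by binomial logistic regression with a family covariate and
    Benjamini-Hochberg q-values; classification of population DMS against a
    two-generation acclimation experiment (stable, inducible, inconclusive;
    expected versus opposite direction; the delta.meth.diff similarity
    statistic and its direction-by-acclimation ANOVA); Weir-Cockerham FST in
    windows around inducible sites with a one-tailed delta.mean.FST
    randomization test; promoter/exon/intron/intergenic annotation with
    nearest-TSS gene association and a per-gene 2x3 Fisher exact test; and a
    synthetic RRBS + VCF scenario generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
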