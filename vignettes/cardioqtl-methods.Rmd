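---
title: "Statistical methods of the cardioqtl pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the cardioqtl pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioqtl)
```

# Scope

`cardioqtl` implements the statistical layer of a case/control cardiac
transcriptome-genetics study — dilated cardiomyopathy (DCM) left-ventricle
samples against non-diseased donor hearts — from normalized expression
through differential expression and exon usage, cis- and condition-specific
eQTL, splicing QTL, allele-specific expression, LD-block GWA enrichment,
functional-annotation enrichment, and a multilocus genetic risk score.
Alignment, transcript quantification, genotype calling/imputation and
latent-factor (PEER) estimation are out of scope; expression principal
components stand in for latent factors.

Because the patient data behind such studies are not redistributable, the
package ships a synthetic cohort generator (`simulate_cohort()`) that
reproduces the *statistical structure* each analysis assumes, so that every
stage is testable end to end.

# Models and tests

## Differential expression

Counts are scaled by a quantile-based factor (`scale_counts_quantile()`,
default upper-quartile: each sample's 75th percentile of non-zero counts is
equalized to the geometric mean of those percentiles; the exact quantile is
a parameter because published variants of the method differ), log
transformed (`log2(x+1)`; base and offset are choices, not doctrine),
residualized on clinical covariates with the mean added back
(`adjust_covariates()`), and tested per gene with a two-sided
Wilcoxon–Mann–Whitney test. A gene is called differential only when the
Benjamini–Hochberg FDR is below 0.05 **and** the absolute difference of
group means exceeds `log(1.2)` — the fold-change gate suppresses
statistically significant but biologically negligible shifts that large
cohorts otherwise produce.

Since every case is recruited at a single centre, centre and disease status
are perfectly confounded; disease status is adjusted implicitly through the
centre covariate, and `adjust_covariates()` warns when an aliased column is
dropped.

## Differential exon usage (PSI)

For each exonic counting part, PSI = inclusion reads / total reads. Only
parts with 0 < PSI < 1 in *every* sample are testable — a part fully
included or skipped in any sample carries no usage contrast. The test
compares the nested Gaussian models

    Full:    PSI ~ group + covariates
    Reduced: PSI ~ covariates

via the exact nested-model F statistic (monotone in the likelihood ratio,
better calibrated at these sample sizes than the asymptotic chi-square).
The differential call uses the double gate FDR < 0.05 and |group beta| >
0.1, i.e. a ten-percentage-point PSI difference.

`simulate_exon_usage_study()` replays the operating-characteristics
simulation: totals from a negative binomial fit to real totals
(`fit_negative_binomial()`, method of moments after discarding counts above
the 90th percentile — note that trimming deliberately biases the fit toward
the bulk of the distribution; it is not an unbiased estimator of the
untrimmed parameters), true PSI uniform on (0,1), a fraction of exons
shifted additively by `delta_psi` in cases (clipped to [0,1]; a
multiplicative reading of "modified by 10%" is available via
`multiplicative = TRUE`), inclusion binomial given the total and true PSI.
Exons removed by the all-samples filter stay in the sensitivity denominator
— otherwise the reported TP/(FN+TP) would not refer to all simulated
differential exons. A replicate with no discoveries contributes FDR 0.

Two consequences worth knowing:

* with heavy-tailed totals (the default NB mean 100, size 1), the
  all-samples filter is extremely strict at n = 205 — a handful of exons
  per 5,000 survive — so the empirical FDR is essentially zero and the
  sensitivity is far below 50%. This is the conservative regime the
  procedure is designed for; the exact sensitivity value depends entirely
  on the totals distribution, which real studies estimate from their own
  data.
* additive shifts that clip at 1 (true PSI > 1 − delta) silently remove
  those exons via the filter; at delta = 0.3 this caps attainable
  sensitivity near 70% even at infinite coverage.

## cis-eQTL

Expression is converted to RPKM, filtered (RPKM > 0 in at least half the
samples), quantile normalized across samples, then each gene is mapped to
standard-normal quantiles with seeded random tie-breaking
(`rank_inverse_normal()`, plotting positions r/(n+1)). The scan fits
`expression ~ dosage + covariates` for every SNP within 1 Mb of the gene
body (edge-to-edge, not TSS; configurable) using Frisch–Waugh
residualization, which is algebraically identical to per-pair `lm` but runs
as matrix operations. Covariates are the measured set (sex, age, RIN,
fibroblast score, centre), genotype PCs, and expression PCs as the
latent-factor surrogate. Significance is flagged at nominal P < 1e-5.

## Condition-specific eQTL

The full model allows separate intercepts and slopes per group,

    y = g(b0 + b1 x) + (1 - g)(b2 + b3 x) + e,

the reduced model forces a common slope. The F test asks whether the slopes
differ; the specificity *call* additionally requires that exactly one of
the two slope 95% CIs contains zero (both excluding zero means the eQTL is
shared even when the slopes differ significantly). An Armitage trend test
on the group-by-genotype table guards against allele-frequency differences
between groups masquerading as condition specificity.

## Splicing QTL

For one gene, one target exon part and one SNP, exon expression values
(quantile normalized across all exons within each sample) enter a linear
model with per-sample terms, per-exon terms, and an interaction letting the
target exon deviate per observed genotype class; the reduced model omits
the interaction. The genotype main effect is constant within a sample and
hence formally unidentifiable next to the per-sample terms: it is absorbed
and contributes no degrees of freedom, leaving df1 = (observed genotype
classes − 1) and df2 = observations − parameters. Genotype classes with
fewer than three carriers are merged into the nearest class first,
mirroring the rare-homozygote folding rule, to avoid df inflation from
singleton classes.

A companion check, `trans_confounding_bound()`, regresses the expression of
a designated trans-acting splicing factor on all sQTL SNPs and reports
Storey's 1 − π0 of the p-value collection as an upper bound on the fraction
of sQTL that could be confounded by that factor.

## Allele-specific expression

Heterozygous sites pass if base quality exceeds 30, coverage is at least
30, both alleles are observed, and the site is in neither mapping-bias
mask. Genome-wide mapping/GC bias is absorbed by testing against each
individual's mean reference ratio rather than 0.5. To stop coverage alone
from driving significance, counts are resampled — a seeded binomial redraw
at n = round(mean total count) with the observed allele fraction (a
deterministic proportional rescaling would be the alternative reading) —
and tested with a two-sided exact binomial test; q-values control the FDR.

The binomial p-values are discrete and the redraw adds sampling noise, so
the per-site p-values are *not* uniform under the null; the meaningful null
guarantees, which the test suite checks, are (i) a conservative call rate
at q < 0.05 and (ii) near-zero rank correlation between original coverage
and significance.

Differential imbalance between groups combines a Fisher exact test on
imbalanced-heterozygote counts with a two-proportion test on pooled allele
fractions; the differential call requires FET p < 0.05 and an absolute
difference in mean alternative-allele ratio above 0.10. Reported
differential sites are LD-pruned greedily (best p first, drop linked sites
at r² > 0.8).

## LD-block GWA enrichment

Variants are grouped into LD blocks as connected components of the r² > 0.6
graph — a reproducible stand-in for the external block service the original
analysis used. Each block is summarized by the smallest (or, as an
outlier-robustness check, second-smallest) GWA p-value of its members, and
blocks containing at least one QTL/ASE variant are compared with the rest
by a one-sided Wilcoxon–Mann–Whitney test.

## Functional-annotation enrichment

Each (SNP, target) pair is labelled 1 when the SNP is the target's top
associated variant; pairs whose SNP is significant for that target but not
its top hit are removed (they are plausibly causal too and would dilute the
contrast as negatives — the exclusion is per target, not global). A
multiple logistic regression of the label on binary annotation features
(five 10-kb distance bins starting at 1 bp, with >50 kb the implicit
reference category and "inside the target" a separate flag; chromatin
states; gene/exon-relative position; ESE hexamer hits via
`match_hexamers()`, 1-based positions) yields per-feature odds ratios, Wald
CIs, and likelihood-ratio p-values; perfect separation is flagged with
unbounded CIs.

## Risk score

`fit_risk_model()` evaluates named SNP candidate sets (plus covariates) by
outer 10-fold cross-validation; within each training split an inner 10-fold
CV on the AUC curve selects the L1 penalty by the one-standard-error rule —
the *largest* lambda within one SE of the best AUC, favouring parsimonious
models — and the refit model is scored on the untouched outer fold. SNPs
enter as dosages. Held-out AUC is never computed on training samples, and
the whole procedure is deterministic given the seed.

# The synthetic cohort

Defaults state the study's world: 97 cases / 108 controls; Hardy–Weinberg
genotypes at MAF drawn from (0.1, 0.5); gene counts negative binomial
(mean 200, size 5 — moderate bulk RNA-seq dispersion) with log-normal
library sizes (sd 0.2) and log-normal baseline spread across genes; exon
totals NB(mean 100, size 1), the heavy-tailed regime of the usage
simulation; inclusion binomial given true PSI; ASE coverage NB(mean 100,
size 10) + 2. All cases share one recruitment centre (perfect
group–centre confounding, as in the study); age and RIN are mildly shifted
in cases (0.3 sd). Planted effects are additive on the log scale for
eQTL/DE (additivity matches the linear models fitted downstream), additive
on the PSI scale for usage/sQTL effects, and a shifted reference fraction
for ASE. One master seed drives per-component child generators, so adding
an effect class never perturbs the other layers.

What the generator does *not* emulate: realistic LD from haplotypes (LD
enters only through explicit pair tables), imputation uncertainty,
read-level artifacts, and the empirical exon-total distribution of any
particular study. A green test therefore establishes correctness of the
statistical machinery under the stated world, not agreement with any
specific dataset's headline numbers.

# Numerical choices

* Nested-model p-values use the exact F distribution throughout.
* `rank_inverse_normal()` uses r/(n+1) positions; ties break by a seeded
  random permutation; a constant vector yields random ranks and a warning.
* `storey_qvalues()` smooths π0 over λ ∈ {0.05, …, 0.95} with a df-3
  spline, falls back to λ = 0.5 on smoother failure, and to plain BH
  (π0 = 1, with a warning) below 100 p-values.
* Fisher odds-ratio CIs are Woolf (log-normal) with Haldane 0.5 correction
  for zero cells.
* For the sQTL power simulations the residual scale matters and is not
  dictated by the model: after within-sample quantile normalization, most
  of the unit total variance sits in the absorbed exon and sample terms, so
  the simulations use exon offsets N(0,1), sample effects N(0,0.7) and
  residual sd 0.3. With residual sd 1 instead, the same planted effect
  (0.5 units per allele, n = 205) is detected at p < 1e-4 only ~35% of the
  time — a property of the design, not of the implementation.
* Coordinates: BED is 0-based half-open; VCF and all reported positions are
  1-based; cis distances are signed from the nearest gene edge and 0 inside
  the gene; strand is carried but ignored.

# Known limitations

* The sensitivity of the exon-usage caller under its own simulation depends
  entirely on the totals distribution; with the default heavy-tailed totals
  the all-samples 0 < PSI < 1 filter leaves very few testable exons at
  n = 205, and per-replicate FDR is then trivially zero.
* `annotation_enrichment()` reports but does not resolve perfect
  separation; rare features deserve exact logistic regression, which is out
  of scope.
* The risk-score module evaluates protocols on synthetic cohorts; the
  original study's absolute AUC values require external GWA genotypes and
  are not reproducible here.
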