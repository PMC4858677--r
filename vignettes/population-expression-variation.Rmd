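---
title: "Methods: population expression variation across common-garden environments"
author: "popExpVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population expression variation across common-garden environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popExpVar)
```

## The problem this package addresses

When a plant population is transplanted from its native habitat into a
harsher common garden, per-gene expression can shift through environmental
induction, through standing genetic variation (haplotypes segregating in
the populations), or through their interaction. `popExpVar` implements a
population-transcriptomics pipeline for exactly this design: the same
genets (clonal individuals) from a set of source populations are grown in
two field sites, one designated *native*, and each ramet is RNA-sequenced,
yielding a genes × samples FPKM matrix, per-sample metadata, and
transcript-coordinate SNP genotypes from the same reads.

The pipeline computes, per gene:

* **population expression level** $E_p$ — the arithmetic mean FPKM over
  the $n$ individuals of one environment;
* **population expression diversity** $E_d$ — a bounded $[0,1]$ index of
  how unevenly expression is spread over individuals;
* **cross-environment variation** — the ratio
  $E_p(\mathrm{new})/E_p(\mathrm{native})$ and the change
  $E_d(\mathrm{new}) - E_d(\mathrm{native})$, with conservation bands and
  a nine-group classification;
* **nucleotide diversity** $\pi$ from the filtered transcript SNPs,
  per environment;
* **haplotype structure** for genes with few SNPs, via an EM phaser;
* **variance partitioning** by two-way fixed-effect ANOVA (environment ×
  population on all genes; environment × diplotype on phased genes), with
  positive-FDR control and an eight-group effect classification.

## Statistical definitions and choices

### Expression level and diversity

$E_p = \frac{1}{n}\sum_i E_i$ with $E_i$ the FPKM of individual $i$. The
default $E_d$ is one minus the evenness of the expression shares
$p_i = E_i / \sum_j E_j$:

$$E_d = 1 - \frac{-\sum_{p_i > 0} p_i \ln p_i}{\ln n}.$$

$E_d = 0$ when all individuals express the gene equally and $E_d \to 1$
as a single individual dominates, so a *larger* $E_d$ means a broader
spread of expression across the population. The index is scale-invariant
(shares only) and permutation-invariant, and a mean-preserving spread
strictly increases it — the three properties the downstream comparisons
rely on. Two alternates are provided (`gini_simpson`, normalised by its
maximum $1 - 1/n$, and `cv`, rescaled as $\mathrm{cv}/(1+\mathrm{cv})$);
the metric used is recorded in the output header.

### Filtering, bands, and grouping

A gene enters the analysis only if it has nonzero FPKM in at least half
of the individuals of *each* environment
(`ceiling(n_env / 2)`). Conservation bands are **inclusive**: a gene is
$E_p$-conserved iff its ratio lies in $[0.5, 2]$ and $E_d$-conserved iff
its change lies in $[-0.25, 0.25]$; endpoints count as conserved because
the bands are stated as closed ranges. The nine-group label is the cross
of the two three-way classes. Equal-count binning (5 groups for $E_p$,
4 for $\pi$ by default) is rank-based with stable tie-breaking; group
sizes differ by at most one, lower-statistic groups take the remainder,
and labels are invariant under strictly monotone transforms, so binning
on $\log_2 E_p$ or raw $E_p$ is identical. Between-bin location
comparisons use the Wilcoxon rank-sum test (exact enumeration when both
groups together have at most 12 untied observations, else the normal
approximation with midrank-tie and continuity corrections).

### Nucleotide diversity

SNPs are filtered with strict thresholds: kept iff quality $> 10$,
missing-genotype fraction $< 0.10$, and minor allele frequency $> 0.05$
over the non-missing alleles (two per diploid) — sites *at* any threshold
are excluded. Per gene,

$$\pi = \frac{1}{L} \sum_{j} \frac{m_j}{m_j - 1} \, 2\hat p_j (1-\hat p_j),$$

the per-site unbiased (Nei) heterozygosity summed over the gene's kept
SNP sites and divided by the transcript length $L$; this equals the
average pairwise allele difference over all $\binom{m_j}{2}$ sampled
allele pairs, which is the oracle the tests compare against. Genes with
no surviving SNPs get $\pi = 0$ and `has_snp = FALSE`. Filtering and
$\pi$ are computed per environment by default (each site's own samples
decide missingness and MAF); a `joint` switch filters once on all
samples. Gene length is a required input (or taken from `##contig` VCF
headers) because assembled-transcript versus covered length is a data
choice the user must own.

### Haplotype phasing

Genes with 1–9 filtered SNPs are phased by an Excoffier–Slatkin EM over
haplotype frequencies: the E-step distributes each individual's genotype
over its compatible unordered haplotype pairs under Hardy–Weinberg
($P\{a,b\} = 2 f_a f_b$, $P\{a,a\} = f_a^2$), the M-step re-estimates
frequencies from expected counts; convergence when the largest frequency
change is below $10^{-8}$ or after 500 iterations, best of several
restarts by log-likelihood, and each individual receives its
maximum-posterior compatible pair (ties broken lexicographically).
Missing genotypes are marginalised over. This is deliberately *not* a
coalescent-prior phaser: the pipeline only consumes best-guess diplotype
labels, and externally phased tables can be supplied instead via
`readPhasedHaplotypes()`. The 9-SNP ceiling reflects the accuracy limit
of phasing short transcript fragments in highly heterozygous material.
In the transplant design the two ramets of a genet share a genotype, so
phasing is done once per genet and the diplotype is shared by both its
samples.

The ANOVA "haplotype" factor is the canonical unordered pair label
(diplotype); levels with fewer than 2 carriers are merged into `rare`
(our addition, to keep the model estimable), and genes with fewer than
two levels after merging are dropped from the haplotype model. Coding
the factor as per-haplotype dosage instead of diplotype label would be a
reasonable alternative; the diplotype label is used because it matches a
"haplotype group" factor in a fixed-effect model.

### ANOVA and multiple testing

Per gene we fit the fixed-effect model $y \sim A \times B$ with
$y = \log_2(\mathrm{FPKM}+1)$ (raw-scale switch available): the log
stabilises the variance of FPKM and matches the generator's scale.
Sums of squares are **Type II** (each main effect adjusted for the other,
the interaction for both), which reduces to the classical balanced
decomposition and remains sensible for the mildly unbalanced design left
by discarded samples. $F$ uses the full-model residual mean square. An
empty factor-level combination makes the interaction inestimable: it is
dropped with a flag rather than failing the gene; a zero residual
variance is flagged degenerate (terms with signal report $p = 0$,
all-zero responses report no test). Implementation note: because the
design is shared across genes, the four nested models are each fit once
by QR and reused for every gene; the per-gene path is cross-checked in
the tests against an independent Type II implementation.

Per term, p-values are pooled across genes and converted to q-values with
Storey's positive-FDR estimator using the fixed-$\lambda$ null proportion
$\hat\pi_0 = \#\{p > 0.5\}/(0.5\,m)$ (capped to $[1/m, 1]$) and step-up
q-values $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$;
Benjamini–Hochberg is the $\pi_0 = 1$ special case. Effect flags use
$q < 0.05$ by default; a raw-$p$ switch exists because published counts
of this kind are often raw-$p$ based, and the eight-group classification
(subsets of {E, H, H×E}) follows whichever convention is configured.

## The synthetic-data generator

No field data ship with the package; every claim is tested on synthetic
data whose generative model is an explicit assumption:

$$\log(\mathrm{FPKM}_{gi} + 1) = \mu_g + \beta_E\,\mathrm{env}_i +
u_{\mathrm{pop}(i)} + h(\mathrm{diplotype}_{gi}) +
\gamma\,(\mathrm{env} \times \mathrm{hap\ or\ pop}) + \varepsilon_{gi},
\qquad \varepsilon \sim N(0, \sigma).$$

Defaults emulate the study design the pipeline targets: 14 populations ×
3 genets × 2 environments (optionally 2 samples discarded per site,
giving 40 per environment), gene baselines
$\mu_g \sim N(3, 1.5^2)$ on the log scale, residual
$\sigma = 0.5$, planted effects of 2 residual SD on 15.4% (environment),
3.0% (population) of genes and 19.9% of SNP-bearing genes (haplotype),
5% interactions, 47% of genes carrying 1–9 SNPs with per-site allele
frequencies drawn from $[0.05, 0.5]$, transcript lengths 300–3000 bp and
2% genotype missingness. Genotypes are drawn under Hardy–Weinberg from a
per-gene haplotype pool; a genet keeps its genotype in both environments
(ramets of one genet), and interaction effects act on
environment × haplotype for SNP-bearing genes and
environment × population otherwise, centred so they do not leak into the
environment main effect for the balanced population design.

FPKM is reconstructed as $e^y - 1$, truncated at zero, so low-baseline
genes naturally produce unexpressed cells for the expression filter to
act on. Two consequences worth knowing:

* values are nonnegative rather than strictly positive, and the
  $\log/\exp$ round trip is exact only on expressed cells;
* genes retaining zero cells after filtering have a point mass at zero
  in $\log_2(\mathrm{FPKM}+1)$, which makes the per-gene $F$-test mildly
  *conservative* on them (measured null rejection 0.03–0.05 instead of
  0.05). The ANOVA-calibration checks therefore draw their null cohorts
  at a high baseline ($\mu_g \sim N(6, 1)$), where no cell truncates and
  the response is an affine transform of the generative linear model;
  the uniformity of default-baseline null p-values is tested separately.

What the generator does **not** emulate: count-level sampling noise
(negative-binomial mean–variance coupling), gene–gene correlation,
population structure and linkage between genes, mapping artefacts, and
environment-dependent SNP calling (genotypes are shared across sites, so
per-environment $\pi$ differs only through per-environment filtering).
Passing tests demonstrate the *methods* behave as specified under the
stated model, not that real field data meet that model.

## Problem sizes and determinism

Test and verification cohorts use 150–2000 genes × 80–84 samples — large
enough that percentage-scale quantities have Monte-Carlo error well
inside the asserted tolerances (a 2000-gene null cohort estimates a 5%
rate with SD ≈ 0.5%; the calibration check pools five such cohorts), and
small enough to run routinely. Every randomised step derives its stream
from a single top-level seed, and `runPipeline()` is byte-identical on
reruns with the same config and seed. All result tables carry a header
line with the package version and a fingerprint of the scientific
configuration (paths excluded).

## Known limitations

* Diploid genotype codes are assumed; paleo-polyploid transcriptomes are
  treated as the VCF presents them.
* The EM phaser ignores recombination and coalescent priors; for long or
  SNP-dense genes an external phaser's best-guess output should be
  supplied instead.
* $E_p(\mathrm{native}) = 0$ genes have an undefined ratio and are
  excluded from ratio-based analyses (kept elsewhere).
* Whether published analyses of this design filtered SNPs jointly or per
  environment is typically unstated; both are implemented, per
  environment being the default.
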