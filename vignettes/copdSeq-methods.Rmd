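---
title: "copdSeq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{copdSeq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdSeq)
```

# Scope

`copdSeq` implements the statistical pipeline of a targeted, internal-standard
(IS) calibrated RNA-seq case-control study of bronchial epithelial cells (BEC)
in COPD: absolute quantification, QC filtering, differential allelic
expression (DAE), cohort co-expression network comparison, a shrinkage-LDA
classifier ranked by correlation-adjusted t-scores, cohort-level statistics,
and GWAS-integration utilities. A synthetic-data generator reproduces the
statistical structure the pipeline assumes, so every stage is testable with
no external data.

# Absolute quantification

Each amplicon assay co-amplifies the native template with a known spike of a
competing synthetic internal standard. Because both templates share primers
and amplification efficiency, the read ratio estimates the molecule ratio:

$$\widehat{\mathrm{mol}} = \mathrm{spike} \times
  \frac{\mathrm{reads}_{\mathrm{native}}}{\mathrm{reads}_{\mathrm{IS}}},$$

and abundance is reported as target molecules per $10^6$ ACTB molecules
measured in the same reaction. The chain is: stochastic-sampling filter
(both templates require `min_reads`, default 20, where Poisson counting CV is
about 22%), reference-gene QC (a sample whose ACTB assay fails the filter
fails entirely, flag `sample_fail`), conversion, normalisation. Missing
cells carry typed reason codes (`native_low`, `IS_low`, `sample_fail`)
because low target expression and assay failure are different phenomena:
the dominant cause of missingness in this design is too few target molecules
loaded into library preparation.

Two numerical facts matter:

* **Ratio bias.** With negative-binomial counts at dispersion $\phi$, the
  double ratio (target over IS, then over the ACTB ratio) has an arithmetic
  bias of roughly $(1 + \mathrm{CV}^2)^2$, about +8–10% at $\phi = 0.05$,
  because $E[1/X] > 1/E[X]$. On the log scale the second-order terms cancel
  and recovery is unbiased; downstream analyses (networks, ANCOVA,
  classifier) therefore work on log abundance.
* **Common-mode normalisation error.** Every assay of a subject shares the
  same measured ACTB denominator. Its measurement error (CV ≈ 0.3 at
  $\phi = 0.05$, dispersion-dominated and independent of depth) is injected
  into all normalised values of that subject, which induces a positive
  correlation floor between all assay pairs. This inflates the edge counts
  of significance-thresholded co-expression networks built on normalised
  abundance, in both cohorts equally. It is a real property of
  reference-normalised competitive-amplicon data, not an artifact of the
  generator.

The representation filter retains assays measured in at least 70% of
subjects (inclusive boundary) before imputation; mean imputation replaces
missing cells with the whole-cohort per-assay mean. This replicates the
conventional pre-CV imputation and leaks a small amount of information
across folds; `cvPooledRoc()` operates on the imputed matrix by design, and
the leak-free alternative is to impute within training folds before calling
it.

# Differential allelic expression

In a heterozygote, genomic DNA carries exactly one copy of each allele, so
the gDNA log2 allelic read ratio varies between individuals only through
analytical noise. cis-regulatory variation adds true inter-individual
variance to the cDNA ratio. The test is an F-ratio of unbiased sample
variances, cDNA over gDNA, referred to $F(n_1 - 1, n_2 - 1)$. The upper
tail is the default alternative (excess cDNA variance is the signal of
interest); a two-sided option exists. Genotypes are called from gDNA counts
with a heterozygote minor-fraction band of [0.25, 0.75] and a homozygote
maximum of 0.05; ambiguous calls are excluded. cDNA samples without a
matched gDNA sample are called from their own counts with a wider band
([0.10, 0.90]) and flagged lower-confidence — a necessity when archival
cDNA outnumbers matched gDNA. All gDNA heterozygotes are pooled as the
control group by default (`matched_only` restricts to matched subjects).
Bonferroni adjustment uses the number of sites in the analysis batch.

# Cohort correlation networks

Pearson correlations of log10 abundance, per cohort, with an edge kept when
the two-sided p of $t = r\sqrt{(n-2)/(1-r^2)}$ is strictly below 0.05 and
using pairwise-complete measured observations (imputed cells are excluded;
`use_imputed` switches). No multiple-testing correction is applied to the
edge filter — the threshold defines the graph, it is not an inference.
Node metrics are degree, shortest-path betweenness normalised by
$(n-1)(n-2)/2$, and harmonic closeness normalised by $n-1$; harmonic
closeness is chosen because thresholded correlation graphs are routinely
disconnected, where classic closeness is undefined. The correlation is
symmetric so the graph is undirected, and "in-degree" and "out-degree"
coincide with total degree. Cohorts are compared metric-wise by two-sided
Wilcoxon rank-sum (exact when sample sizes permit without ties), and
individual gene pairs by the Fisher r-to-z test,
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

# Shrinkage LDA and CAT scores

With 30 subjects per class and ~35 features, the sample covariance is
ill-conditioned; the classifier therefore uses James–Stein-type shrinkage:

* pooled per-feature variances are shrunk toward their median with an
  analytic variance-minimising intensity;
* the feature correlation matrix is shrunk toward the identity,
  $R_\lambda = (1-\lambda) R + \lambda I$, with the analytic
  (Schäfer–Strimmer form) intensity clipped to $[0, 1]$, guaranteeing a
  positive-definite covariance for any $\lambda > 0$.

The correlation-adjusted t-score vector is
$\tau = R_\lambda^{-1/2}\, t$ (symmetric inverse square root by
eigendecomposition), where $t$ is the shrunken-variance two-class
t-statistic. Features are ranked by $|\tau|$, with ties broken by feature
name for determinism. Demographic covariates (sex as 0/1, age in years,
pack-years) enter as ordinary features on their natural scales — LDA is
affine-equivariant given full covariance handling, so standardisation is
unnecessary.

Evaluation is pooled stratified 10-fold cross-validation: for each
candidate feature-set size (1–15), features are re-ranked within each
training fold, the top-$s$ model fitted, and out-of-fold posterior
probabilities pooled; the size with the best pooled AUC (rank statistic,
ties half-credit) wins, smaller size on ties. Note that the *maximum* over
candidate sizes is optimistically biased under the null — the pooled AUC of
a fixed size is the unbiased quantity, which is how the null-calibration
test is phrased. The AUC confidence interval is a stratified percentile
bootstrap (2000 replicates; the reference method is unstated so this
package commits to one). The classification cut-point maximises the Youden
index $J$ over score midpoints; optionally the median threshold over
repeated stratified CVs (50 repeats in the acceptance script). The
diagnostic odds ratio uses the Wald CI with Haldane–Anscombe 0.5 correction
on zero cells.

A known limitation, documented deliberately: selecting the size by maximum
pooled AUC is unstable when many null features dilute the candidate set.
On a 12-feature panel with 6 signal features at the study's sample size the
selected set recovers the truth (Jaccard ≥ 0.5) in about 9 of 10
replicates; on a 30-feature panel at the same discrimination the recovery
rate drops severely because noisy AUC maxima favour both very small and
very large sizes. Interpret the *membership* of the selected set
cautiously on wide panels.

# Cohort statistics

Fisher exact tests (probability-mass two-sided rule) for categorical
demographics, pooled-variance Student t for continuous ones (Welch by
flag), and ANCOVA for covariate-adjusted expression differences: the
covariate enters the model before the group term so the sequential F for
group is covariate-adjusted; covariates are looped one at a time. With no
covariate the ANCOVA reduces exactly to the pooled t-test. Expression is
log10-transformed first. The DAE enrichment comparison of two proportions
uses the N−1 chi-squared test, $(ad-bc)^2(N-1)/[(a+b)(c+d)(a+c)(b+d)]$ on
1 df — the recommended small-sample form, equal to $(N-1)/N$ times
Pearson's statistic. Both published background proportions (lung
5884/19725 and lymphoblastoid 2935/9751) are computed because the
reference value does not identify which was used.

# GWAS integration

Interval conventions are stated because they are the usual silent bug:
interval tables (regulatory regions, gene spans) are BED-style 0-based
half-open; SNP positions are 1-based (VCF convention) and converted on
ingestion. Restriction and gene intersection use interval-tree overlap
(`IRanges`), sub-quadratic in input sizes; gene intersection extends spans
by a configurable flank (default 10 kb) and annotates all overlapping gene
labels. Significance filtering is strict (`p < alpha`). D′ is computed
from haplotype counts, $D' = |D|/D_{\max}$; D′ = 1 means at most three
haplotypes are observed (complete linkage). Chromosome-naming mismatches
between SNP and interval tables raise an error listing the offending names
rather than silently dropping everything.

# The synthetic cohort

`simConfig()` defaults emulate the targeted study design and are the
conditions under which the package's properties are demonstrated:

* 30 COPD / 30 control subjects; demographics mirror the clinical table
  margins (P(male) 22/30 vs 11/30, ages N(64, 5), pack-years higher in
  COPD, spirometry consistent with the case definition FEV1/FVC < 0.7 and
  FEV1% < 80).
* 68 assays over 35 genes (ACTB reference included), fixed per-assay
  baseline log2 abundances spanning ~60 to ~50,000 molecules per $10^6$
  ACTB so that the low tail falls under the dropout threshold (100
  molecules) in a fraction of subjects — missingness arises from latent
  abundance, not at random, matching the stated cause of missingness in
  this assay class.
* latent per-subject log2 abundance is multivariate normal, SD 1, with
  within-gene correlation 0.3; the COPD cohort adds 15 gene-disjoint assay
  pairs at r = 0.6 (gene-disjointness keeps the implied matrix positive
  definite), giving the COPD cohort more latent co-expression structure.
* group shifts of ±0.45 log2 on the six classifier genes (KEAP1 down, the
  rest up). This effect size was calibrated once so that the full
  pipeline's pooled 10-fold CV AUC averages ≈ 0.75 at n = 30+30 — the
  operating point of the study the package targets.
* read counts are negative binomial (dispersion 0.05) around
  depth × molecules/spike, with IS depth $10^5$; depths and spikes are not
  stated by the reference design and are configurable defaults.
* five measured SNP sites at the classifier genes' reference MAFs
  (0.34, 0.11, 0.11, 0.09, 0.30) with cis effect β = 1 on the logit scale:
  heterozygote cDNA allele fractions shift by β·g for a ±1 regulatory
  phase, gDNA fractions stay at 0.5 with logit SD 0.15 (the analytical
  noise floor), binomial read sampling on top, depth $10^4$.

What the generator does **not** emulate: amplification-efficiency
differences between alleles (mapping bias), batch effects, RNA degradation
gradients (the 5′/3′ integrity statistic is exercised on constructed
fixtures), phasing structure beyond a single linked regulatory allele, and
real LD patterns in the GWAS tables. Passing tests demonstrate the
statistics behave as designed under the assumed structure; they do not
validate the biology of any particular dataset.

# Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data at the
study's own scale (60 subjects, 68 assays; 150 subjects for DAE), with
Monte-Carlo properties at 100–1000 replicates of small instances and
brute-force oracle comparisons on instances small enough to enumerate.
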