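---
title: "Probabilistic TWAS: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic TWAS: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptwas)
```

## The causal question

Transcriptome-wide association studies ask whether genetically regulated
expression of a gene causes variation in a complex trait. `ptwas` frames
this as instrumental-variable (IV) analysis: cis-eQTL variants serve as
instruments for a gene's expression $X$, and their association with the
trait $Y$ is evidence for a causal path $X \to Y$, provided the usual IV
assumptions hold — the instruments are real eQTLs (inclusion), they are
independent of confounders (randomization, supplied by Mendelian
inheritance), and they act on $Y$ only through $X$ (exclusion
restriction, i.e. no horizontal pleiotropy).

The package operates on a two-sample design: eQTL effects are learned in
one cohort (genotypes + expression) and the trait association is
evaluated in a non-overlapping GWAS cohort (genotypes + trait, or
summary statistics). Under a two-sample design weak instruments bias
estimates toward zero rather than inflating type-I error, which shapes
several choices below.

## Probabilistic eQTL annotations

All stages consume a three-level Bayesian fine-mapping annotation of
each gene's cis-region:

* candidate association models $M_i$ (SNP subsets) with posterior model
  probabilities $P_{M_i}$;
* SNP-level posterior inclusion probabilities (PIPs),
  $p_j = \sum_{M_i \ni j} P_{M_i}$;
* signal clusters $S_k$ — sets of SNPs in LD representing the same
  underlying causal eQTL — with signal-level PIPs (SPIPs)
  $q_k = \sum_{j \in S_k} p_j$.

Annotations can be read from a DAP-style text file
(`read_annotation()`) or produced by the built-in fine-mapper
(`finemap()`), a conjugate Bayesian multiple-regression model scored in
closed form (Gaussian effect prior with variance $v\sigma^2$ per
standardized effect, scale prior $p(\sigma^2) \propto 1/\sigma^2$).
Defaults: per-SNP prior inclusion $1/p$, $v = 0.25$, models up to five
SNPs. The search is a deterministic beam search (width 4) over forward
extensions with a one-step swap refinement of the best model; the entire
scored frontier is retained, which is what spreads posterior mass across
LD partners of each selected SNP. Each frontier is capped at its 64
best extensions: models below that cap carry no appreciable mass but,
uncapped, thousands of them would distort the truncated normalization.
An exhaustive enumeration mode serves as the oracle on small loci
(p ≤ ~15); the test suite requires greedy PIPs within 0.02 of exhaustive
PIPs on simulated loci.

Clustering is greedy: SNPs visited by decreasing PIP (ties by SNP id,
making the result order-invariant); a SNP joins a cluster when its $r^2$
with the cluster seed is at least `r2_min` (default 0.25), and SNPs with
PIP below `pip_floor` (default 0.01) stay unclustered. These two
thresholds are package decisions — fine-mapping software does not agree
on a single rule — and the downstream statistics depend only on cluster
membership and PIP sums. When a file carries no cluster records and no
LD is available, clusters are reconstructed from model co-occurrence:
SNPs that never appear together in a retained model are alternative
explanations of one signal; SNPs that co-occur represent distinct
signals.

## The composite IV and the scan test

For hypothesis testing the package builds one strong instrument per gene
by Bayesian model averaging over the fine-mapped models. Each model is
fit by OLS in the eQTL cohort, giving per-SNP effects
$\hat\beta_{M_i,j}$ (zero outside the model), and the composite weight
is

$$w_j = \sum_i P_{M_i}\, \hat\beta_{M_i,j},$$

so the composite score $\hat x = \sum_j w_j G_j$ equals the
posterior-weighted ensemble of per-model least-squares predictions of
expression. Weights are computed on centered, *unstandardized* dosages,
keeping $w_j$ in expression units per allele; reference genotype
standard deviations $s_j$ from the eQTL panel are stored alongside. The
ensemble identity ($\sum_j w_j G_j = \sum_i P_{M_i}\hat x_{M_i}$) is
asserted to $10^{-10}$ in the tests.

With individual-level GWAS data the scan is a simple regression of the
trait on $\hat x$ (two-sided normal p-value from slope/SE). With summary
statistics only, the scan is the burden form

$$z = \frac{\sum_j w_j s_j z_j}
         {\sqrt{\sum_{j,k} w_j w_k s_j s_k R_{jk}}},$$

with $R$ a reference LD matrix shrunk as $(1-\lambda)R + \lambda I$,
$\lambda = 0.05$ by default, to guard against reference-panel mismatch.
Marginal GWAS z-scores embed each SNP's residual trait variance, so for
very strong signals the summary and individual-level scans agree
relatively (within ~10% of $|z|$) rather than absolutely; at moderate
signal strength the tests require $|\Delta z| < 0.2$ on matched panels.
`gini()` summarizes weight sparsity; composite weights concentrate on
the few causal SNPs (Gini near 1) while still sharing weight within LD
clusters.

## Estimating the gene-to-trait effect

Estimation deliberately uses only *strong* instruments: signal clusters
with SPIP at or above `spip_min` (default 0.50). Within a cluster with
member PIPs $p_i$ and SPIP $q$, each member SNP yields a Wald/2SLS ratio
$\hat\beta_{xy,i} = \hat\beta_{\mathrm{gwas},i}/\hat\beta_{\mathrm{eqtl},i}$
with the two-term delta-method variance
$\sigma^2_{xy,i} = se_g^2/\hat\beta_e^2 +
\hat\beta_g^2 se_e^2/\hat\beta_e^4$. The member ratios are combined by
the conditional causal probabilities $\tilde p_i = p_i/q$:

$$\hat\beta_{xy} = \sum_i \tilde p_i\, \hat\beta_{xy,i}, \qquad
  \mathrm{Var}(\hat\beta_{xy}) =
  \sum_i \tilde p_i\,(\sigma^2_{xy,i} + \hat\beta_{xy,i}^2)
  - \hat\beta_{xy}^2,$$

the laws of total expectation and total variance. The variance term
carries the residual uncertainty about *which* member SNP is causal, and
is nonnegative by construction. Cluster-level estimates from independent
signals are combined by fixed-effect inverse-variance weighting
(`ivw_combine()`). Marginal (single-SNP) eQTL betas are used in the
ratios: the summary-statistic workflow only has marginal effects, and
for well-separated clusters the marginal and joint fits coincide.

Two comparators are built in: the SMR-style estimator (top single eQTL
SNP by |z|, same Wald ratio) and a z-test built from the IVW estimate
and its standard error.

## Exclusion-restriction diagnosis

Independent eQTL signals are independent measurements of the same causal
effect; inconsistency among them indicates pleiotropy. Across clusters
with SPIP ≥ `spip_min` the package computes Cochran's
$Q = \sum_k (\hat\beta_k - \hat{\bar\beta})^2/\hat\sigma_k^2$ and

$$I^2 = \max\!\left(0, \frac{Q - T + 1}{Q}\right),$$

with $T$ the number of instruments. $I^2$ is reported as a quantitative
metric only — no hypothesis test is attached, because the natural null
("effects are heterogeneous") cannot be meaningfully tested with a
handful of instruments, and "accepting" the homogeneity null of the
usual Q test is a statistical mistake. The pipeline flags gene-tissue
records with $I^2$ above `i2_exclude` (default 0.5) and drops them from
the estimate table; genes with a single eligible instrument are
estimated with $I^2$ recorded as 0 by convention. The same Q/I² machinery
applies across tissues (`cross_tissue_i2()`) where large values suggest
genuine tissue specificity rather than pleiotropy.

## Multi-tissue combination

Per-tissue scan p-values for one gene test a global null (no effect in
any tissue) via the Cauchy combination (ACAT),
$T = \sum_i w_i \tan((0.5 - p_i)\pi) / \sum_i w_i$, valid under
arbitrary dependence; weights are uniform across tissues (no principled
asymmetry between tissues at the testing stage). P-values below
$10^{-15}$ enter through the Cauchy tail approximation
$\tan((0.5-p)\pi) \approx 1/(p\pi)$ to avoid overflow. FDR across genes
is controlled with Storey q-values: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed with a cubic spline and read off
at $\lambda = 0.95$; below 100 p-values the estimate falls back to
$\pi_0 = 1$ (Benjamini–Hochberg) with a warning, since $\pi_0$
estimation is unstable in small batches.

## The simulation framework

`sim_scenario()` fixes the study conditions: 706 individuals split into
400 (eQTL) and 306 (GWAS, disjoint); 1000 genes; 1500 cis-SNPs per gene;
causal eQTL indicators Bernoulli(0.002) — three causal eQTLs per gene on
average — with effects $N(0, 0.5)$; a polygenic background over all SNPs
scaled per gene so expression heritability is about 50% (when the
realized sparse effects alone exceed the target, no background is added
and heritability exceeds 50%, mimicking the dependence on realized
allele frequencies); unit-variance residuals. The trait follows the
structural equation $y = u + \eta x + e$, $e \sim N(0,1)$; power
experiments draw $\eta \sim N(0, \phi^2)$ with $\phi^2$ assigned in
equal numbers from $\{0, 0.2, 0.5, 0.8, 1, 1.2\}$ (the proportion of
null genes is a package decision — one sixth — as no canonical mixture
exists), and estimation experiments fix $\eta = 1$.

Genotypes are synthetic: each haplotype follows a latent Gaussian AR(1)
process across SNPs (correlation `ld_decay`, default 0.85), thresholded
at the allele-frequency quantile (MAF ~ Uniform(0.05, 0.5)) and summed
into dosages. This yields geometrically decaying LD but **not** the
long-range block structure, allele-frequency spectrum, or
cross-population quirks of real genotype panels, and that matters for
absolute benchmarks: real cis-regions produce wider signal clusters and
weaker, more redundant instruments. Consequently the synthetic
instruments are *stronger* than real-data equivalents — Wald ratios have
roughly half the sampling error seen with real LD — so absolute RMSE
levels and power gaps between estimator-based tests reproduce only up to
this gap, while calibration (type-I error, unbiasedness), orderings
driven by instrument aggregation, and all monotone trends (RMSE falling
with SPIP threshold, I² falling with instrument strength) are faithful.
Passing simulation benchmarks therefore validates the statistical
machinery, not the real-data magnitudes.

The heterogeneity experiment injects a severe exclusion-restriction
violation into half the genes: one causal eQTL SNP receives a direct
per-allele trait effect of magnitude `pleiotropy_sd` (default 1, the
same scale as the mediated effect $\eta\beta$) with random sign. The
severity is a package decision: the diagnosis targets severe departures,
and a fixed magnitude keeps the experiment interpretable.

## Numerical choices and degenerate inputs

* Fine-mapping ties in the log marginal break by SNP index; the search
  is fully deterministic.
* Zero-variance and linearly redundant genotype columns are dropped with
  warnings; singular within-model designs in weight building fall back
  to a small ridge.
* Scan p-values are floored at the smallest positive double, so perfect
  association does not overflow.
* Clusters with nonpositive SPIP or missing member Wald ratios are
  errors; fewer than two eligible clusters makes the I² diagnosis
  not-applicable (`NULL`) rather than an error, and no eligible cluster
  makes a gene not-estimable (`NULL`) rather than an error.
* Weak instruments (|eQTL z| < 1e-6) are refused in the Wald ratio.
* LD matrices feeding quadratic forms are shrunk toward identity; a
  nonpositive quadratic form is reported as an LD inconsistency error
  with advice to increase the shrinkage.

## Problem sizes used in the checks

The packaged checks run at reduced but faithful scale: the estimation
benchmark simulates 400–500 genes (≥300 passing the scan), the power
benchmark 500 genes, and the null-calibration benchmark 300 genes, all
at the full 1500 SNPs and the 400/306 sample split. Unit tests use small
loci (10–40 SNPs) where exhaustive enumeration and quadrature oracles
are available.

## Known limitations

* The fine-mapper is a lightweight stand-in for full adaptive DAP-style
  shotgun searches; exact agreement with DAP-G output is not a goal, and
  its truncated model space slightly biases PIPs for very weak signals.
* Summary-statistic estimation assumes marginal eQTL betas; clusters of
  highly correlated SNPs spanning *different* signals would violate the
  marginal-equals-joint approximation.
* The delta-method Wald variance is near-exact for strong instruments
  (the tests check it against a Monte-Carlo oracle at |z| = 10 within
  10%) but underestimates ratio dispersion for instruments near the
  SPIP eligibility boundary, which lifts I² slightly above its
  theoretical null mean.
* Storey's π0 estimate needs a few hundred p-values to stabilize; the
  BH fallback is deliberately conservative.
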