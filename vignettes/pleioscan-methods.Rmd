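---
title: "Methods: the cross-trait shared-gene pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cross-trait shared-gene pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The problem

Two complex diseases can share susceptibility genes even when neither trait's
GWAS flags those genes genome-wide significant on its own: the per-SNP signal
is diluted across many correlated variants, and the two studies are never
jointly analysed. `pleioscan` screens for such genes in three stages, each of
which only needs data a desk analyst can obtain: per-SNP summary statistics
(rsID and p-value) for each trait, a reference genotype panel to estimate
linkage disequilibrium (LD), a gene annotation, and public case-control
expression series for the two diseases.

## Stage 1: the LD-aware gene-based test

**Model.** For a gene with member SNPs $1..n$, each per-SNP p-value $p_i$ is
converted to the upper-tail $\chi^2_1$ statistic
$q_i = F^{-1}_{\chi^2_1}(1 - p_i)$, and the gene statistic is
$T = \sum_i q_i$. If the members were independent, $T \sim \chi^2_n$ under
the null; they are not, so the null is simulated: draw
$z \sim \mathrm{MVN}(0, \Sigma)$ with $\Sigma$ the $n \times n$ matrix of
signed Pearson correlations $r$ between panel dosage vectors, and use
$\sum_i z_i^2$ as one null replicate. The empirical p-value is
$(r + 1)/(m + 1)$ where $r$ counts replicates *strictly* exceeding $T$
(ties do not count as surpassing) out of $m$ — the standard
positively-biased estimator that can never return 0.

**SNP-to-gene assignment.** A SNP is a member if it lies inside the gene
interval (boundaries inclusive, optional `padding_bp`, default 0 — i.e. gene
boundaries themselves, no kb window), or if its squared correlation with any
positional member exceeds `r2_link` (default 0.8, strict `>`). Two open
choices were resolved as follows: LD recruitment is evaluated against
*positional* members only (not transitively against recruited ones), and
candidates are restricted to the gene's chromosome, since panel LD across
chromosomes is sampling noise. Both thresholds are exposed as arguments.

**Numerics.** Finite panels produce numerically indefinite correlation
matrices, so $\Sigma$ is repaired by clipping eigenvalues at $10^{-8}$ and
renormalising the diagonal to 1 before the Cholesky factorisation; missing
dosages are mean-imputed per SNP and monomorphic SNPs are dropped (a gene
whose members are all monomorphic is reported untested, not an error).
P-values of exactly 0 are clamped at ingest to $10^{-300}$ because the
$\chi^2_1$ quantile diverges at 0; $p = 1$ maps to a contribution of 0.

**Adaptive schedule.** Simulation sizes escalate through
$m = 10^3, 10^4, 10^5, 10^6$ (configurable, capped by `max_sims`), stopping
once at least 10 null exceedances are seen: genes with unremarkable
statistics stop cheaply at $10^3$, while promising genes earn resolution down
to $p \approx 10^{-6}$. Each gene's stream is seeded from a stable hash of
(global seed, gene symbol), so results are independent of gene iteration
order and of SNP input order (members are canonically ordered by position
before $\Sigma$ is built).

## Stage 2: Fisher's method with layered Bonferroni control

Genes with $p < 0.05$ (strict) in *both* traits form the overlap set of size
$n$. Each overlapping gene's two p-values are combined with Fisher's
statistic $x^2 = -2\sum_{i=1}^{k}\ln P_i \sim \chi^2_{2k}$ ($k = 2$ here,
though `fisher_combine()` accepts any $k \ge 1$), and the combined p-value is
compared — strictly, at full precision, rounding only at output — against the
layered threshold $0.05/(2n)$. The factor 2 is deliberate: it spends one
extra multiplicity layer on the two-trait family and is exposed as
`bonferroni_factor` should a user prefer the plain $0.05/n$.

## Stage 3: expression concordance

For every candidate gene and every expression study (log2 scale, assumed
normalised upstream), the package reports $\mathrm{logFC} =
\bar{x}_{case} - \bar{x}_{control}$ and a two-sided two-sample test. The
default is the pooled-variance t test — the unmoderated core of the standard
microarray linear-model workflow — with Welch and limma's empirical-Bayes
moderated t as options; the choice matters little at the sample sizes
involved and the pooled default keeps the statistic hand-checkable. Missing
values are handled complete-case within each group; a group with fewer than
two usable samples yields a flagged `NA`. With $G$ genes under test, a gene
is `any_significant` if some study gives $p < 0.05/G$ (strict), and
`shared_significant` if at least one study of *each* disease does. Repeated
measures within a series (e.g. several time points per patient) are treated
as independent samples, matching the practice of the analyses this package
systematises; raw (unadjusted) per-study p-values enter the rule. Per gene
and disease the smallest-p study is also reported as the representative
result.

## The synthetic-data generator

The generator exists so that every stage can be validated offline against
known truth; its defaults are fixed study conditions, not tuning knobs.

* **Panel.** 503 individuals — the size of the 1000 Genomes European panel
  the method is normally run against — carrying 200 gene blocks of 10 SNPs.
  Within a block, haplotypes come from an AR(1) Gaussian copula with latent
  adjacent correlation $\rho = 0.8$ (strong within-block LD, the regime in
  which LD-aware nulls matter), thresholded at allele frequencies drawn
  $U(0.05, 0.5)$ and summed into diploid dosages; blocks are independent.
  The copula was chosen over haplotype resampling because only the LD
  correlation structure matters to the gene test, and the thresholded-copula
  dosage correlation can be checked against a brute-force Monte Carlo oracle.
* **GWAS.** Association z-scores are drawn per block from
  $\mathrm{MVN}(\lambda, \Sigma_{block})$ with $\Sigma_{block}$ the realised
  panel LD, $\lambda = 0$ at non-causal SNPs and $\lambda = 4$ per SNP at the
  five shared-causal genes; $p = 2\Phi(-|z|)$. Simulating summary statistics
  directly (rather than case-control phenotypes) matches the abstraction the
  pipeline consumes and makes null calibration exact.
* **Expression.** Four studies sized like typical public case-control series
  (12/15, 10/10, 39/24, 69/23), $\sigma = 0.5$, per-gene baselines
  $N(8, 2^2)$, planted logFC 1 at the causal genes.

What the generator does *not* emulate: realistic allele-frequency spectra,
recombination maps, population structure, imputation noise, probe-level
artefacts, or array normalisation. Passing tests therefore demonstrate the
statistical machinery — calibration, LD handling, recovery of planted
signal — not robustness to real-data preprocessing.

## Validation design and problem sizes

The test suite checks each component against an independent oracle: the
$\chi^2_1$ conversion against a numeric root-find on the survival function;
the simulated null against closed forms ($\chi^2_1$, $\chi^2_n$ under an
identity $\Sigma$, $n\cdot\chi^2_1$ under perfect LD); the single-SNP gene
against its own SNP p-value at $m = 10^6$ (within 3 Monte Carlo standard
errors); Fisher's method against the $k=1$ identity and the df-4 closed form
$(1 + x/2)e^{-x/2}$; the t tests against `stats::t.test` and a hand-computed
example; and the generator's dosage LD against a $10^5$-draw Monte Carlo
oracle. Calibration tests run 200 genes under the global null
($m = 10^3$ per gene, Kolmogorov–Smirnov uniformity); the end-to-end
recovery experiment runs 20 replicates of the default 200-gene scenario with
$m$ capped at $10^4$ — at the planted effect size the per-trait p-values sit
at the Monte Carlo floor, so a larger cap changes nothing but runtime — and
requires sensitivity ≥ 0.8 and FDR ≤ 0.2 on the recovered shared-gene set,
pooled across replicates.

The bundled example tables let two further end-to-end checks run on real
published numbers: every printed combined p-value of the 24 MS/IS shared
genes reproduces at three significant figures from its per-trait pair, and
the published expression matrix reclassifies to the printed 16
any-significant genes and the five shared genes (*CAMK2G*, *CLEC2D*,
*FOXP1*, *LBH*, *SLC2A4RG*).

## Known limitations

* The gene test's resolution is bounded by `max_sims`; p-values at the
  Monte Carlo floor are reported as $1/(m+1)$, a lower bound rather than an
  estimate.
* Fisher's method assumes the two traits' gene p-values are independent;
  overlapping GWAS control cohorts would violate this and inflate combined
  significance.
* The expression stage inherits whatever probe-to-gene mapping and
  normalisation the input matrices carry; it implements no preprocessing.
* The MHC region receives no special handling despite its extreme LD; genes
  there share top SNPs and their tests are strongly dependent.
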