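---
title: "Models and methods behind regulatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regulatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulatlas)
```

regulatlas builds a multi-tissue atlas of gene regulatory variation for a
structured panel of inbred lines — the setting of crop diversity panels
assayed by RNA-seq in several tissues — and links that atlas to complex
traits. This vignette explains each model the package fits, the parameters
that matter, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Tissue-specific expression

For each gene, expression is `log2(count + 1)`, scaled to mean 0 and
variance 1 across *all* samples pooled over tissues. One tissue at a time we
fit

$$y = \mu + X b + e,$$

where `X` codes the tested tissue as +1 and every other tissue as −1, and
keep the t-statistic of `b`. Pooling before scaling matters: the contrast is
"this tissue against the rest of the organism", not within-tissue variation.
The t-statistic from this ±1 coding is identical to the pooled two-sample
t-statistic for tissue-versus-rest, which is what the test suite asserts.

Per tissue, the top 5% of genes by t enter as candidates (ties at the cutoff
are all retained; the count is `floor(0.05 g)` otherwise) and a candidate is
called *specific* when its median fold change against the other tissues
reaches 2. Fold change is computed on the count scale with a pseudocount of
1 — `(median_t + 1) / (median_o + 1)` against each other tissue `o` — and
"median fold change" is read as the median of those per-tissue ratios. The
alternative reading (tissue median against the median of the other tissues'
medians) is available via `fc_method = "ratio_of_medians"`. The pseudocount
keeps genes silent in most tissues well-defined; with counts in the tens,
its bias is negligible.

Gene-set enrichment of the resulting lists is the standard upper-tail
hypergeometric test against a user-supplied universe, with
Benjamini–Hochberg FDR across sets and the fold of enrichment
`(k/n)/(K/N)`. The package deliberately ships no organism annotation:
gene sets come in as GMT files.

## The mixed-model core

Every variance-structured fit in the package goes through one REML routine:

$$y = C\beta + u + e, \qquad u \sim N(0, \sigma_u^2 R), \quad
  e \sim N(0, \sigma_e^2 I).$$

`R` is whichever relationship matrix the analysis calls for: genomic kinship
(GRM) for association scans, identity-by-state (IBS) for population
structure, the line-incidence cross-product for multi-environment BLUPs, or
the transcriptomic (omics) relationship matrix `A = ZZ'/g` for variance
partitioning and TWAS. `R` is eigendecomposed once; after rotating `y` and
`C` by the eigenvectors the covariance is diagonal in
`h = sigma_u^2 / (sigma_u^2 + sigma_e^2)`, and the restricted likelihood is
profiled over `h` on (0, 1) by bracketed scalar optimization
(`stats::optimize`, tolerance 1e-9, with the interval endpoints checked so
boundary solutions are kept). The intraclass correlation `rho2` — the PVE
when `R` is the ORM — is `h` itself; its standard error comes from the
numerical curvature of the profile restricted log-likelihood at the optimum.

Two degenerate situations are handled explicitly. When `R` is proportional
to the identity the two components are aliased, the profile is exactly flat,
and the fit returns `converged = FALSE` with `rho2 = NA` (scans then fall
back to ordinary least squares). Negative eigenvalues down to numerical
noise are clipped at zero; an IBS estimate with per-variant missing-pair
exclusion can be mildly indefinite, which the constructor reports with a
warning rather than an error.

### Association scans and conditional analysis

The default scan mode is EMMAX-style: variance components are fit once under
the null model, and each variant is tested by GLS with
`V = sigma_u2 R + sigma_e2 I` held fixed — the same approximation the
GCTA-mlma toolchain uses, and the right cost/accuracy trade-off at thousands
of genes times thousands of variants. An `exact` mode refits the components
per variant for verification. Wald p-values use the normal reference, the
convention in mixed-model GWAS at these sample sizes. The test suite pins
the scan to a dense-inversion GLS oracle at relative 1e-8 and checks the
type-I error (null variants under population structure) stays in a 3-sigma
binomial band around 0.05.

Conditional analysis repeats the scan, each round adding the smallest-p
variant below the threshold to the fixed covariates, until nothing passes —
the stepwise loop run on individual-level data (summary-statistic
conditioning needs an external LD reference and is out of scope here). Ties
break by p, then position, then variant id, so the output is deterministic;
perfectly collinear candidates are skipped with a warning.

### Multiple testing

Genome-wide thresholds are `alpha / Me`, with the effective marker number
`Me` estimated from the eigenvalues of the variant correlation matrix in
sliding windows (default 200 variants, overlap 50): each window contributes
`sum(1(lambda >= 1) + (lambda - floor(lambda)))` (the Li–Ji rule), a
window's contribution is spread uniformly over its variants, and overlapped
variants average their shares. Eigenvalues within 1e-9 of an integer are
snapped to it so that analytic fixtures (orthogonal dosages, duplicated
pairs) come out exactly — M independent markers give exactly M, duplicated
pairs exactly M/2. Transcriptome-wide thresholds are `0.05/g` (strict) and
`0.05/n_associated` (lenient, from the realized count of associated genes —
the realized-count rule is used because a fixed published count only applies
to its own dataset).

## eQTL atlas

Per tissue, each gene's standardized expression is scanned against all
variants with the tissue's latent factors as fixed covariates and kinship as
the random effect; significant genes then undergo the conditional loop, so
independent signals are enumerated with a round number. Standardizing
expression puts effect sizes in SD units and makes them comparable across
tissues.

Latent factors are the first k = 25 left singular vectors of the
standardized expression matrix, scaled to unit variance — a deterministic
surrogate for Bayesian hidden-factor estimators, used here purely as
nuisance covariates where the two approaches behave nearly identically.
Factors are estimated after standardization and passed as covariates (no
pre-residualization): expression standardization is needed first for
comparable effect sizes, and conditioning is equivalent to residualizing up
to the fixed-effect projection.

A record is *cis* when its variant lies within 1 Mb of the gene's TSS on the
same chromosome (inclusive at the boundary), else *trans*. eQTLs from
multiple tissues are grouped into one regulatory signal when connected by a
chain of pairs with dosage-LD r² strictly above 0.2 and distance strictly
below 500 kb (union of connected components; LD is r² on the full panel —
the toolchain convention — and D' is not used). Each cluster's
representative is its smallest-p member. Cross-tissue comparison pairs
effects for (gene, cluster) combinations seen in two tissues and reports the
Pearson correlation and the opposite-sign fraction.

## Trait integration

**PVE.** The ORM `A = ZZ'/g` over standardized log2 expression enters the
REML core directly; the PVE of a trait is the fitted intraclass correlation.

**TWAS.** Each gene's expression is a fixed effect with random-effect
covariance `sigma_u2 A + sigma_e2 I` fit once under the null — the
mixed-model TWAS that guards against inflation from transcriptome-wide
correlation structure.

**Colocalization.** A published trait QTL and an eQTL cluster colocalize
when the QTL position and the cluster representative's position are on the
same chromosome strictly less than 100 bp apart. The representative (not any
member) is compared by default — `match = "any"` relaxes this — because the
representative is the cluster's best-supported causal candidate.

**SMR.** With the top eQTL as instrument, the expression-to-trait effect is
`b_xy = b_GWAS / b_eQTL`, tested with
`T = z_GWAS^2 z_eQTL^2 / (z_GWAS^2 + z_eQTL^2)` against chi-square(1); the
delta method gives `se_xy`.

**HEIDI.** Under a single shared causal variant every cis instrument implies
the same `b_xy`; under linkage of distinct causal variants they differ. For
instruments besides the top (eligible: eQTL p < 1.6e-3, r² with the top
within [0.05, 0.9], capped at 20 by eQTL significance — the method's
published defaults), the statistic is the sum of squared standardized
differences `d_i = b_xy(i) - b_xy(top)`. The covariance of the `d` vector
follows the first-order (delta-method) expansion with
`cov(b_i, b_j) = r_ij se_i se_j` within each scan and independence across
scans; the null distribution — a weighted sum of chi-squares with weights
from the eigenvalues of the correlation of the standardized differences — is
approximated by Satterthwaite moment matching. The homogeneous case
(`d = 0` exactly) short-circuits to p = 1.

That first-order covariance is exact only when each instrument explains a
vanishing share of the expression variance. The mediation-null calibration
experiment therefore lives in the weak-instrument regime (per-gene
expression R² about 1%: effect 0.1 SD at n = 10,000, a 30-SNP LD block,
eQTL and GWAS statistics from disjoint cohorts), where the test holds its
nominal size. On stronger instruments the same implementation rejects
noticeably above nominal — a property of the method's first-order
approximation, worth remembering when interpreting HEIDI on strong eQTLs.

**Set-versus-random comparisons.** Colocalized eGenes are compared with the
remaining TWAS-tested genes by a two-sided rank-sum test on −log10 p
(robust to the heavy right tail), plus an empirical p from size-matched
random gene draws; SNP-set PVE is compared against size-matched random
variant sets by the empirical exceedance fraction, with
`(1 + #{exceed}) / (1 + n_draws)` so p is never exactly zero. Draws are
without replacement and seeded.

**Replication.** Gene–trait pairs are re-tested in an independent panel by
Pearson correlation of expression and trait across lines; the summary is the
fraction with p below 0.05, with sign consistency reported separately when
discovery signs are supplied.

## Multi-environment BLUPs

Replicated phenotypes are reduced to one value per line by
`value = mu + environment (fixed) + line (random) + e`, fit with the same
REML core (the line effect enters through the incidence cross-product), and
the returned BLUP is the shrunken line deviation
`sigma_l^2 Z' V^{-1}(y - C beta)`. In the balanced case this equals the
line-mean deviation times `sigma_l^2 / (sigma_l^2 + sigma_e^2 / r)`, which
the tests check against both the closed form and an independent lme4 fit.

## What the synthetic data emulate — and what they do not

`simulate_genotypes()` produces biallelic dosages with LD from a haplotype
copying process (each variant copies the previous allele with probability
`1 - switch_prob`, fresh draws at block and chromosome starts), so adjacent
r² is tunable by a single parameter and dosages stay in the exact {0, 1, 2}
domain. Population structure comes from logit-normal subpopulation shifts of
the base allele frequencies. One scenario seed drives deterministic
sub-streams per component, so outputs are bit-reproducible.

`simulate_expression()` writes log2-scale expression as baseline +
planted eQTL effects (cis within 1 Mb of the assigned TSS, trans elsewhere;
effects in SD units on standardized dosage; optionally shared across tissues
with an opposite-sign fraction) + tissue-specific boosts + shared-loading
latent factors + Gaussian noise, then exponentiates and rounds to counts —
matching the log2-then-standardize treatment downstream. A small fraction of
genes get near-zero baselines so detection filters have something to do.
Defaults (baseline N(6, 1.5²) log2 counts, noise SD 0.5, factor loadings
N(0, 0.5²)) were chosen once as plausible bulk RNA-seq magnitudes.

`simulate_trait()` mixes a genetic part, a transcriptomic part (weighted
causal-gene expression in one tissue) and noise, scaled empirically so the
transcriptome fraction hits `target_rho2` exactly in-sample.

Not emulated: realistic recombination maps or demography, sequence-level
reads, count overdispersion beyond the log-normal, batch structure beyond
the latent factors, and missing genotype calls (the readers and kinship
estimators handle missingness; the generator does not produce it). Passing
tests on these simulations show the estimators are correct under their own
assumptions — they do not certify behavior under, say, heavy-tailed counts
or assay artefacts.

## Problem sizes in the shipped experiments

The recovery and calibration experiments run at deliberately moderate sizes,
chosen as the smallest panels at which each property is cleanly identified:
mixed-model calibration at n = 300 lines × 2,000 null variants; PVE recovery
at n = 300, g = 1,000 over 20 replicates (an unstructured panel with a fully
polygenic transcriptomic trait and no latent factors — the intraclass model's
own data-generating process, since REML on a Marchenko–Pastur-like ORM
spectrum is only weakly identified and confounded designs roughly double its
sampling spread); specificity recovery at 4 tissues × 75 lines × 1,000
genes; the end-to-end atlas at n = 300, m = 5,000, g = 1,000, 3 tissues with
100 planted eQTLs of 1 SD; and the HEIDI null at 500 replicates of the
weak-instrument regime described above.

## Known limitations

- The EMMAX approximation understates uncertainty for variants of large
  effect; use `mode = "exact"` where that matters.
- HEIDI inherits the first-order covariance approximation discussed above
  and is anti-conservative on strong instruments.
- The Satterthwaite tail is accurate near conventional thresholds but not
  deep in the tail; extremely small HEIDI p-values are indicative only.
- Factor correction by truncated SVD can absorb genuine broad *trans*
  signals (as any hidden-factor correction can); planted-truth recovery
  tests use cis-dominated architectures for that reason.
- `Me` from windowed eigenvalues approximates, not reproduces, any
  particular published estimator of the effective test count.
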