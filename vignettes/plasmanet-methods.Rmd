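---
title: "Methods: dissecting plasma protein regulation with plasmanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting plasma protein regulation with plasmanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmanet)
```

## Overview

`plasmanet` analyses how plasma protein levels are regulated by three
layers acting in tissues: cis-genetic variation at the coding gene, the
transcription of the coding ("seed") gene itself, and the collective
activity of gene co-expression modules (gene-regulatory networks, GRNs).
The package provides the statistical stages of that analysis and a
synthetic-data generator that plants all three mechanisms with known
parameters, so that each stage — and the pipeline as a whole — can be
validated by parameter recovery rather than by eyeballing real data.

This vignette documents the models, the tunable parameters, the
assumptions baked into the generator, and the numerical and design
decisions, in that order.

## cis-QTL mapping

For a gene with transcription start site (TSS) at position $s$, the cis
window is $[\max(1, s - 500\,\mathrm{kb}),\; s + 500\,\mathrm{kb}]$, both
ends inclusive. SNPs are filtered before mapping: any SNP with a missing
dosage in any sample is removed, then any SNP with empirical minor allele
frequency (MAF) below 0.05, where MAF $= \min(\hat p, 1 - \hat p)$ and
$\hat p = \overline{\text{dosage}}/2$.

Each retained (SNP, feature) pair inside the window is tested by simple
linear regression of the phenotype on the additive dosage with an
intercept. Dosages are deliberately **not** standardized: effects are per
minor allele, which makes eQTL and pQTL effect sizes directly comparable
in the coherence analysis. The t statistic uses $n - 2$ degrees of
freedom with a two-sided p-value. Multiple testing is controlled by
Benjamini–Hochberg step-up FDR at 5%, by default over all cis pairs of a
phenotype class jointly (one family per tissue for eQTLs, one for plasma
pQTLs); a per-feature family is available for sensitivity analysis.
Pairs whose dosage is constant within the analysis samples are skipped
and counted rather than reported with degenerate statistics.

## Allelic coherence of shared e/pQTLs

A SNP "shared" between an eQTL and a pQTL means the **same SNP id** is
FDR-significant in both scans; when several SNPs are shared for a
(protein, tissue) pair the one minimizing $\max(p_e, p_p)$ is classified.
With $m = \max(\beta_e, \beta_p)$ and $d = |\beta_e - \beta_p|$:

* $m < 0$: both effects negative — negatively coherent;
* $m > 0$ and $m > d$: both positive — positively coherent;
* $m > 0$ and $m < d$: opposite signs — divergent.

The rule is algebraically identical to sign logic off the tie set, and
the suite verifies that equivalence on a dense grid of effect pairs. The
ties $m = 0$ or $m = d$ occur only when one beta is exactly zero — a
measure-zero event for continuous estimates — and are conservatively
classified divergent and flagged.

Because each tissue is compared with plasma pairwise, a protein can
receive several coherence calls (one per sharing tissue). The simulator
draws per-tissue eQTL effects independently, so cross-tissue sign
agreement on synthetic data is weaker than in real cohorts where eQTL
effects are largely shared across tissues; coherence fractions computed
on simulation should be read with that in mind.

## Colocalization

Summary statistics (per SNP: effect $\hat\beta$, variance $V$ of
$\hat\beta$, MAF, sample size) for two traits are aligned on shared SNP
ids within a ±100 kb window of the TSS. The Wakefield approximate Bayes
factor for one SNP is

$$\log \mathrm{ABF} = \tfrac12 \log(1 - r) + \tfrac12 z^2 r, \qquad
  r = \frac{W}{W + V},\; z^2 = \hat\beta^2 / V,$$

with effect-prior variance $W = 0.15^2$ for quantitative traits. Per-SNP
log-ABFs are combined into the posterior over the five
single-causal-variant hypotheses (H0 none, H1/H2 one trait only, H3 two
distinct variants, H4 one shared variant) with per-SNP priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the canonical defaults, since
the analysis this package implements used the method's standard settings.
All sums are evaluated in log space (log-sum-exp), so extreme signals
($|z| = 40$ and beyond) remain finite; the H3 term uses a log-difference
that is exactly $-\infty$ for a single-SNP region, giving
$\mathrm{PP.H3} = 0$ identically there. A region is called colocalized
when $\mathrm{PP.H4} > 0.5$ (the explicit form of the "PP > 0.5"
criterion). SNP alignment assumes consistently oriented alleles; a strict
mode errors when the traits disagree on MAF by more than 0.05, the only
harmonization signal available in the summary schema.

The coloc window (±100 kb) is narrower than the QTL discovery window
(±500 kb); both are honored as stated by the analysis being reproduced,
and both are parameters.

## Variance explained by independent cis-SNPs

From a protein's FDR-significant pSNPs, a greedy pruner sorts by
ascending p-value (ties by SNP id, for determinism), keeps the best
remaining SNP and discards every remaining SNP with $|r| > 0.8$ dosage
correlation against it. Absolute correlation is used although the
underlying workflow states "Pearson r > 0.8" without sign handling:
negatively correlated dosages are equally redundant. The protein is then
regressed on all retained dosages jointly and the **adjusted**
coefficient of determination $1 - (1 - R^2)(n-1)/(n-k-1)$ is reported; it
may be negative, and a protein with no significant pSNP is reported as
undefined, never as zero. Near-collinear dosage columns surviving the
pruner are dropped by QR pivoting with a message.

## Seed-gene association

Spearman's $\rho$ is the Pearson correlation of average ranks; p-values
use the large-sample t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, matching the reference implementations
at cohort-scale $n$; an exact permutation p-value is available for
$n \le 10$. Constant vectors are flagged as undefined rather than
returning a fabricated value.

Multiple testing across the (tissue, gene, protein) family uses
Storey–Tibshirani q-values: $\hat\pi_0(\lambda)$ is computed on the grid
$\lambda = 0.05, 0.10, \ldots, 0.95$, smoothed by a 3-df smoothing spline
and read off at $\lambda = 0.95$, clipped to $(0, 1]$; then
$q = \hat\pi_0 \cdot \mathrm{BH}(p)$, which is monotone in $p$ and equals
BH when $\hat\pi_0 = 1$. With fewer than 100 tests the $\hat\pi_0$
estimate is too unstable and the conservative $\hat\pi_0 = 1$ fallback is
used with a message. The marginal family pools all tissues by default
(the original analysis does not state its pooling; a per-tissue family is
available by flag).

The multivariate model fits, for each protein $Y$,
$Y = \beta_0 + \sum_t \beta_t X_t + \varepsilon$ over the samples present
in **all** tissue datasets and the protein matrix, with one covariate per
tissue where the transcript is expressed. Per-coefficient t-tests are
pooled into one q-value family across proteins × tissues. Collinear
transcript columns are dropped with a warning; proteins with no
measurable transcript are excluded and counted. This is the adjustment
that separates a tissue's direct contribution from associations induced
by cross-tissue expression correlation, and the suite verifies on
planted data that bystander-tissue associations lose significance after
adjustment.

## Network (eigengene) association

A module's eigengene is the first principal-component score of its
standardized member expression (members are (gene, tissue) pairs, so a
cross-tissue module mixes columns from several tissue matrices restricted
to their common samples). Scores are rescaled to unit variance and the
sign is fixed so the mean correlation with members is non-negative —
determinism across linear-algebra backends, since singular vectors are
defined only up to sign. Constant members are dropped with a warning.
Modules are classified tissue-specific when purity (largest
single-tissue member fraction) is ≥ 0.95, with the boundary counted as
tissue-specific ("threshold of 0.95" does not state strictness; ≥ is the
inclusive reading).

Module memberships are consumed as input tables and eigengenes are
recomputed from expression rather than imported: that choice is what
makes the stage testable on synthetic data, where the latent module
factor is known.

The permutation null shuffles the sample labels of each eigengene
independently in every round and recomputes the full Spearman grid. This
preserves the protein–protein correlation structure while breaking every
eigengene–protein link; the pooled permuted p-values should be — and are,
in the suite — uniform. The exact permutation construction of the
original analysis is not described; this scheme is a declared choice.
Default 1000 rounds, seeded.

Each protein's category is the class of its strongest significant
association (largest $|\rho|$ among records with $q \le 0.05$; ties by
smaller q, then lexicographic predictor id): seed gene, tissue-specific
GRN, cross-tissue GRN, or none.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
reference study used in validation.

**Genotypes.** Each SNP's dosage counts minor alleles under
Hardy–Weinberg equilibrium: a latent standard normal is thresholded at
$\Phi^{-1}((1-p)^2)$ and $\Phi^{-1}(1-p^2)$ for MAF $p$. Within an LD
block the latents follow an AR(1) process with correlation `ld_rho`, the
simplest generator with tunable, analytically checkable LD (the suite
compares adjacent-SNP dosage correlation against a Monte-Carlo
integration of the thresholded copula). MAFs are uniform on
[`maf_low`, `maf_high`] with `maf_low` ≥ 0.05, because rarer variants are
excluded by the analysis anyway. No missing genotypes are generated — the
workflow being emulated removed any SNP with missingness. Genes sit 1 Mb
apart on one chromosome with SNPs within ±400 kb of the TSS, so
neighbouring cis windows do not capture each other's SNPs.

**Expression.** Gene $g$ in tissue $t$ is
$\beta_{gt} \cdot \text{dosage(causal SNP)} + \ell \cdot f_m +
\varepsilon$, where $f_m$ is the module latent factor (standard normal
per sample, shared by members) and $\ell$ = `module_gene_loading`. Module
effects on proteins act **through the factor**, not through individual
member genes, which is what makes "network drives protein" separable from
"seed gene drives protein" in recovery tests.

**Proteins.** Protein $=\sum_t w_{pt}\,\text{expr(seed gene}, t) +
\sum_m \gamma_{pm} f_m + c\,\text{dosage} + \varepsilon$. When a target
genetic variance fraction is set, the direct coefficient $c$ is solved so
the in-sample $R^2$ of the protein on its causal SNP equals the target
exactly (the orthogonal residual decomposition makes this closed-form);
the realized fraction is recorded. A protein whose seed gene is expressed
nowhere and has no direct effect is generated as pure noise and flagged.

**Summary pairs.** For colocalization testing, per-SNP
$\hat\beta, V$ pairs are generated over independent SNPs with
$V = 1/(2 n \,\mathrm{maf}(1-\mathrm{maf}))$ and a causal z-score of
`effect_z` plus standard normal noise, under shared / distinct /
single-trait / null configurations.

**Defaults** (the reference study): 500 samples, 200 genes, 7 tissues
(labelled LIV, BLOOD, SKLM, SF, VAF, AOR, MAM), 50 SNPs per gene in
blocks of 10 with `ld_rho` = 0.6, eQTL effect SD 0.7, seed weights in
[0.5, 1], 20 modules of 25 members (half tissue-specific, half
cross-tissue), eigengene effect SD 1, member loading 0.8, noise SD 1.
Sample size and the 90-protein 30/30/30 split match the validation
design; the effect scales were chosen once so that planted signals are
comfortably detectable at $n = 500$ without being trivial (per-allele
$R^2$ of a typical eQTL around 10–20%, protein–eigengene correlations
around 0.5–0.7).

**What the generator does not emulate**: realistic human LD maps,
population structure and relatedness, imputation uncertainty, and the
error structure of proximity-extension (NPX) assays — protein noise is
Gaussian, an assumption flagged rather than claimed. Passing recovery
tests therefore demonstrates the correctness and calibration of the
statistical machinery under the stated model, not robustness to every
artefact of real cohort data.

## Numerical choices and degenerate inputs

* All OLS paths go through QR (or closed-form single-regressor algebra
  verified against normal equations to 1e-10); rank deficiencies are
  reported with the offending columns, not silently absorbed.
* Colocalization sums use log-sum-exp; the H3 weight uses
  `log(exp(a) - exp(b))` computed as `a + log1p(-exp(b - a))`, returning
  $-\infty$ when the difference underflows.
* BH ties and LD-pruning ties are broken by stable sorts on (p, id);
  category ties by (|ρ|, q, id). Identical inputs always give identical
  outputs.
* Residualization on covariates is idempotent and orthogonal to the
  design to 1e-10; zero-variance features are dropped with a warning.
* Every simulator function consumes an explicit seed and restores the
  caller's RNG state; sub-stages use fixed offsets from `rng_seed` so
  regeneration is bit-for-bit identical.

## Validation problem sizes

The acceptance suite runs: oracle equivalence on 100 random instances per
regression engine (tolerance 1e-10); 50 random 50-SNP colocalization
regions against direct enumeration (1e-8) plus 50 shared-causal and 50
distinct-causal scenario replicates at $|z| = 8$, $n = 5000$; 50
variance-explained replicates at a planted fraction of 0.20 with
$n = 500$ and a 200-protein recovered-vs-true slope; a dense coherence
grid; type-I calibration of the QTL scan (1000 null pairs at $n = 1000$),
a 100 × 100 null Spearman grid at $n = 500$, and a 10,000-value permuted
eigengene null (slope and Kolmogorov–Smirnov distance); 100 uniform-null
and 20 spiked-mixture q-value replicates at $m = 10{,}000$; 50 random
modules against a full-SVD eigengene oracle; and one full reference study
(500 × 200 × 7 × 50, 20 modules, 90 proteins) scored for category
recovery. These sizes keep the whole suite under a minute of simulation
time while leaving the statistical checks well-powered.

## Known limitations

* Only single-causal-variant colocalization is implemented (no
  multi-signal or conditional analysis), and no allele harmonization
  against a reference panel beyond the MAF consistency check.
* Trans-QTLs, covariate-in-model QTL regression (covariates are handled
  by residualization upstream), and stepwise conditional QTL analysis are
  out of scope.
* Module inference itself (co-expression clustering, key-driver
  analysis) is not performed; memberships are inputs.
* The coherence analysis aggregates tissues pairwise against plasma; a
  per-protein multi-tissue summary is derivable from the per-tissue calls
  but no single-number cross-tissue aggregation is imposed, since the
  source description of that aggregation is ambiguous.
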