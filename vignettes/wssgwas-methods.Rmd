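---
title: "Weighted single-step GWAS: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In most livestock populations, phenotypes and pedigree are abundant while
genotypes exist only for a small, recent subset of animals.  Single-step
GBLUP (ssGBLUP) evaluates all animals jointly by replacing the pedigree
numerator relationship matrix A with a hybrid matrix H that blends A with
the genomic relationship matrix G over the genotyped subset.  Weighted
single-step GWAS (WssGWAS) then converts the genotyped animals' estimated
breeding values (GEBVs) into per-SNP effects, re-weights SNPs by their
apparent contribution to genetic variance, iterates, and finally reports
the percentage of genetic variance attributable to fixed 1-Mb genomic
windows.  This package implements that full chain for traits with maternal
effects — the typical situation for lamb body weights, where the dam
contributes both genes (maternal genetic effect) and a repeatable
environment (maternal permanent environment).

# The model

Records are modelled as

$$
\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{a} +
\mathbf{W}\mathbf{p} + \mathbf{S}\mathbf{m} + \mathbf{e},
$$

with fixed effects b (sex, birth type, herd, birth year, dam age class, all
categorical, first level dropped for identifiability), direct additive
effects $\mathbf{a}\sim N(0,\mathbf{K}\sigma^2_a)$, maternal genetic
effects $\mathbf{m}\sim N(0,\mathbf{K}\sigma^2_m)$ attached to the dam,
maternal permanent-environment effects
$\mathbf{p}\sim N(0,\mathbf{I}\sigma^2_p)$ per dam, and residuals
$\mathbf{e}\sim N(0,\mathbf{I}\sigma^2_e)$.  K is A for pedigree BLUP and H
for single-step runs.  The direct-maternal genetic covariance is fixed at
zero; the model statement lists four independent variance structures, and a
covariance term would change the MME block structure.  A configuration
switch could later relax this.

Weaning weights are standardized to 90 days before analysis:
`adjust_weaning_weight(ww, bw, age) = (ww - bw)/age * 90`.

## Relationship matrices

* `build_A()` uses the tabular method; `build_A_inverse()` uses Henderson's
  rules with Meuwissen-Luo inbreeding.  Inbreeding is always included:
  multi-generation pedigrees accumulate nonzero F, and ignoring it biases
  the Mendelian-sampling variances.  Unknown parents are unrelated
  founders; genetic groups are out of scope.
* `build_G()` is the (weighted) VanRaden matrix
  $G = ZDZ'/\sum_i 2p_i(1-p_i)$ with Z the gene content centered as
  $0-2p, 1-2p, 2-2p$.  We center and divide by the *counted-allele*
  frequency (mean count / 2) rather than literally the minor-allele
  frequency: G is invariant to which allele is counted under this coding,
  so the two conventions coincide up to relabelling.
* `blend_G()` forms $G_\omega = \alpha G + \beta A_{22}$ with defaults
  $\alpha = 0.95$, $\beta = 0.05$.  Blending is not cosmetic: with
  observed-frequency centering the ones vector lies in the null space of
  $Z'$, so unblended G is always singular.
* `build_H_inverse()` assembles
  $H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G_\omega^{-1} -
  A_{22}^{-1}\end{pmatrix}$ as a scatter-add, so genotyped animals may sit
  anywhere in the pedigree ordering.  Dense symmetric factorization is used
  for $G_\omega$ and $A_{22}$; at a few hundred genotyped animals sparse
  genomic inverses (APY etc.) are unnecessary.

## REML

`estimate_varcomps_reml()` maximizes the restricted likelihood through the
mixed-model-equations identity
$-2\ell = \log|R| + \log|G| + \log|C| + \mathbf{y}'P\mathbf{y}$, evaluated
with one sparse Cholesky factorization per iteration (`Matrix`).  The
default method takes average-information (AI) steps with step-halving and
falls back to an EM-REML update whenever the AI proposal leaves the
parameter space or fails to increase the likelihood; `method = "em"` gives
the pure, provably monotone EM iteration.  The trace terms
$\mathrm{tr}(K^{-1}C^{uu})$ are computed by chunked solves of the factored
coefficient matrix against identity columns of each random-effect block.
Components that head to zero are pinned at $10^{-8}\,\mathrm{var}(y)$; a
run that exhausts `max_iter` returns the last iterate with a warning.
Analytic scores were verified against numeric derivatives of the dense-V
restricted likelihood, and the MME-based likelihood itself is tested for
exact equality with the dense computation.

## The weighting iteration

Starting from $D = I$, each iteration t:

1. $G_{(t)} = \lambda Z D_{(t)} Z'$ with
   $\lambda = 1/\sum_i 2p_i(1-p_i)$; blend; build $H^{-1}$.
2. Solve the MME for all animals' direct and maternal GEBVs.
3. Back-solve SNP effects
   $\hat{u}_{(t)} = \lambda D_{(t)} Z' G_{\omega(t)}^{-1} \hat{a}_g$
   (direct) and the analogue from $\hat m_g$ (maternal).  The *blended*
   matrix is inverted — the same one whose inverse enters $H^{-1}$ —
   because the raw $\lambda ZDZ'$ is singular (see above).
4. nonlinearA weights: $d_i = 1.125^{\min(|\hat u_i|/sd(\hat u),\,7) - 2}$,
   i.e. the exponent is capped at 5, bounding weights in
   $[1.125^{-2}, 1.125^{5}] \approx [0.79, 1.80]$ and preventing runaway
   weights.
5. Rescale the new weights so their sum (the trace of D) is preserved,
   keeping the total genetic variance captured by G constant.

Three iterations are the default.  Weight updates are driven by the direct
effects only: the scheme uses a single D matrix and a single loop, and
maintaining one D per effect type would give each trait-effect its own G.
Maternal SNP effects are re-estimated each iteration under the shared D.

## Window decomposition

`window_variance()` assigns every SNP to a fixed, non-overlapping bin of
`window_bp` (default 1 Mb): bin k of a chromosome covers base pairs
$[(k-1)\cdot 10^6 + 1,\ k\cdot 10^6]$ (1-based inclusive, the PLINK map
convention).  The window's share of genetic variance is
$100\cdot\mathrm{var}(\sum_j Z_j\hat u_j)/\sigma^2$, the variance taken
across genotyped individuals, with $\sigma^2_a$ (direct) or $\sigma^2_m$
(maternal) in the denominator.  `top_windows()` returns the k highest
windows, ties broken in genome order.  Coordinate-anchored bins (rather
than SNP-count or sliding windows) were chosen because the reported
first/last SNP positions inside each bin then carry the SNP-density
information directly.

# The synthetic study

`sim_config()` defines the desk-scale study all tests run against:

* 400 founders plus 4 discrete generations of 100 matings with 4 offspring
  each — 2,000 animals, ~1,600 records, ~400 dams.  Four recorded progeny
  per dam are what make $\sigma^2_p$ separable from $\sigma^2_m$: with
  only two records per dam the two maternal components are nearly
  confounded and REML medians drift in opposite directions.
* 5,000 unlinked SNPs on 5 chromosomes of 100 Mb; founder frequencies
  uniform on [0.05, 0.5]; gene-dropping inheritance (each offspring allele
  drawn uniformly from the parent's pair).
* 5 direct and 5 maternal QTL drawn among the SNPs, their effects rescaled
  so the QTL jointly explain 50% of the respective genetic variance; the
  rest is an infinitesimal polygenic term bred down the pedigree with
  Mendelian-sampling variance $(0.5 - 0.25(F_s + F_d))\sigma^2_{poly}$.
* Variance components (2, 1, 0.5, 4) kg² for direct, maternal genetic,
  maternal permanent environment and residual — direct h² ≈ 0.27, in the
  range reported for lamb body weights.
* 75% of the last generation (300 animals) released as the genotyped
  panel, with 1% genotypes masked at random; the QC + imputation stages
  then mirror a real analysis.

What the generator deliberately does *not* emulate: linkage and LD (SNPs
are unlinked; windows only need coordinates), selection and assortative
mating, genotyping-batch artifacts.  Consequences for interpreting green
tests: with no LD, marker data add almost nothing to GEBV accuracy at
n = 300 genotyped / m = 5,000 SNPs (single-step accuracy equals
pedigree-BLUP accuracy here), so QTL-localization performance in this
sandbox understates what the method achieves on real 50K data where LD
concentrates marker signal.  Conversely, parameter-recovery results
(REML) transfer well, because the phenotype generator matches the fitted
model exactly.

# Numerical choices and edge cases

* Positions are 1-based inclusive throughout; window bin k covers
  $[(k-1)\cdot 10^6 + 1, k\cdot 10^6]$.
* The Hardy-Weinberg filter uses the exact conditional test (the PLINK
  default), summing probabilities of heterozygote counts no more likely
  than the observed one; it is checked against an independent
  factorial-arithmetic enumeration.
* QC order: map (unmapped/sex-chromosome SNPs) → individual call rate →
  SNP call rate → MAF → HWE, the conventional PLINK order; the thresholds
  default to 0.95 / 0.95 / 0.05 / 1e-6.
* Missing genotypes are imputed by Hardy-Weinberg draws at the observed
  frequency, seeded and reproducible.  Haplotype-based imputation is out
  of scope; at ≤5% missingness in a ~300-animal panel the downstream
  effect on G is negligible.
* Ties in `top_windows()` resolve to genome order; `sd = 0` in the weight
  update returns unit weights with a warning; an REML component at the
  floor is reported at the floor rather than zero so logs stay finite.
* The `.ped/.map` text route carries no allele labels, so the reader
  counts the lexicographically smallest observed allele; a SNP observed
  monomorphic for the other allele reads back with flipped coding.  The
  binary `.bed/.bim/.fam` route stores both alleles and round-trips
  losslessly.

# Problem sizes used by the test-suite

Unit tests run on pedigrees of 3-500 animals and panels up to a few
hundred SNPs, against dense-algebra oracles (explicit V-matrix GLS,
explicit H, gene-dropping Monte Carlo with $10^5$ replicates).  The
end-to-end property checks use the full desk-scale preset: variance
recovery over 20 generator seeds and QTL-window localization over 25
seeds, chosen as the smallest replication that makes medians and hit
rates stable.

# Known limitations

* No direct-maternal genetic covariance (switchable in principle, not
  implemented).
* Single-trait analyses only; BW and WW are run separately.
* No LD-aware simulation, hence no realistic assessment of imputation or
  of LD-driven localization gains.
* Unknown-parent groups and metafounders are not supported.
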