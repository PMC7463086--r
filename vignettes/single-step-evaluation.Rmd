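---
title: "Single-step genomic evaluation: models, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation: models, design choices, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgblup)
```

## The evaluation problem

National beef evaluation programs predict the additive genetic merit
(breeding value) of every animal — including young candidates that have no
phenotype of their own — from three sources of information: the pedigree,
the phenotypes of relatives, and, increasingly, dense SNP genotypes.
Traditional pedigree BLUP (pedBLUP) uses only the first two. Single-step
genomic BLUP (ssGBLUP) folds genotypes into the same linear mixed model so
that genotyped and non-genotyped animals are evaluated jointly, which is
the practically attractive route when only part of the population is
genotyped. This package implements both, plus the metrics used to quantify
how much the genomic step helps, and a simulator that produces populations
on which every claim can be checked against known truth.

## Model and algebra

Both methods fit the multiple-trait animal model
$y = Xb + Zu + e$ with $\mathrm{var}(u) = G_0 \otimes K$ and
$\mathrm{var}(e) = R_0 \otimes I$, solved through Henderson's mixed-model
equations (MME). Concretely:

* **Pedigree side.** Pedigrees are validated and topologically sorted
  (parents before offspring, stable within ties; parents that never occur
  as animals are added as founders). Inbreeding coefficients come from the
  Meuwissen–Luo algorithm; the sparse $A^{-1}$ is assembled directly by
  Henderson's rules using Mendelian-sampling variances
  $d_i = 0.5 - 0.25(F_s + F_d)$, with $0.75 - 0.25F$ when one parent is
  known and $1$ for founders. Unknown parents are treated as unrelated
  founders and an animal with an unknown parent side has $F = 0$; this is
  the standard treatment when no genetic-group structure is modelled.
* **Genomic side.** Dosages pass quality control (monomorphic markers,
  minor allele frequency strictly below 5%, marker call rate below 90%,
  then animals above 10% missingness, then genotype-based parentage
  conflicts above a 1% opposite-homozygote rate). Frequencies use
  non-missing calls only; missing dosages are imputed to their marker mean
  $2p_j$ before centering, which contributes exactly zero to the genomic
  relationship matrix. $G = WDW'/2\sum_j p_j(1-p_j)$ with $W$ the centered
  dosages and $D$ identity unless marker weights are supplied.
* **Single-step side.** $H^{-1} = A^{-1}$ plus
  $\tau G^{-1} - \omega A_{22}^{-1}$ in the genotyped block. $G$ is blended
  with $A_{22}$ as $0.95\,G + 0.05\,A_{22}$ before inversion, which keeps
  it positive definite when markers are fewer than animals. Defaults are
  $\tau = \omega = 1$; both are exposed because published analyses
  occasionally quote other values — one source we follow reports
  "default" $\tau = \omega = 0.05$, which does not match the defaults of
  any mainstream implementation and resembles blending weights instead,
  so the package keeps $\tau$, $\omega$ and the blending weight
  independent rather than guessing intent.
* **Solving.** The MME are assembled sparsely with trait-major ordering of
  genetic effects and a residual precision matrix built per animal from
  the inverse of the $R_0$ submatrix of its observed traits — the exact
  treatment of missing multi-trait records. Fixed factors use reference
  coding (first level dropped) so the equations are full rank; breeding
  values are invariant to that choice. Prediction error variances are the
  corresponding diagonal entries of the inverse coefficient matrix,
  computed exactly by a dense factorization. That is the reason the
  package targets desk scale (roughly $2\times10^4$ equations): the
  per-animal accuracy metric needs the exact inverse, so no iterative
  solver is offered.

## Variance components

Genetic parameters come from EM-REML on the pedigree model. Each iteration
solves the MME at the current $(G_0, R_0)$ and updates
$G_{0,st} \leftarrow (\hat u_s' A^{-1} \hat u_t +
\mathrm{tr}(A^{-1} C^{uu}_{st}))/q$ and, per trait pair, the residual
covariance from observed residual cross-products plus the matching
prediction-variance corrections, averaged over the animals recorded for
both traits. Updates falling outside the positive-semidefinite cone are
projected back by eigenvalue clipping. EM was chosen over
faster-converging alternatives because its monotone restricted likelihood
is directly assertable in tests; the trace is recorded every iteration.
With missing multi-trait records the per-pair averaging is the standard
practical treatment, and the monotonicity guarantee is asserted only on
complete-record runs. Starting values split the observed phenotypic
(co)variance evenly between $G_0$ and $R_0$; the default stopping rule is
a maximum relative component change below $10^{-6}$ within 500 iterations.
Near a boundary maximum ($\sigma^2_a \to 0$) EM converges sublinearly, so
null-variance checks run a fixed 250 iterations instead of waiting for the
relative-change rule.

Heritability is $h^2_t = G_{0,tt}/(G_{0,tt}+R_{0,tt})$; genetic and
phenotypic correlations come from $G_0$ and $G_0 + R_0$.

## Accuracy metrics

Two metrics, reported per trait and stratum:

* $r_{M1}$ — the Pearson correlation between pedigree EBVs and single-step
  GEBVs over an animal set. A population-level agreement measure.
* $r_{M2} = \sqrt{\max(0, 1 - \mathrm{PEV}/V_A)}$ — the per-animal
  accuracy implied by its prediction error variance. The additive variance
  $V_A$ is taken from a pedigree-only REML fit and shared by both methods,
  so differences in $r_{M2}$ reflect only the information entering the
  PEV. The underlying reliability expression is sometimes printed without
  the square root in the applied literature; the square-root (accuracy)
  form is used here.

Percent accuracy change between methods is computed on unrounded stratum
means and only rounded for display, because tables rounded before the
ratio produce visibly inconsistent percentages.

## The simulator: what it emulates, and what it does not

The generator mirrors the structure of a proven-bull testing scheme:

* Discrete generations (default 600 founders plus three generations of
  800) with a small sire pool per generation (25), so a minority of sires
  accumulate large progeny groups and earn the proven-bull (PBULL) label
  at 10+ progeny. The youngest generation splits into candidate bulls
  (CBULL, 30%) and young calves (YBULL).
* Unlinked biallelic markers (default 2,000; founder MAF uniform on
  0.05–0.5) gene-dropped through the pedigree, so Mendelian transmission
  is exact by construction. A random 200 of them act as QTL: their
  multi-trait effect vectors are drawn normal and rescaled so the
  frequency-weighted effect covariance equals the target $G_0$ exactly,
  making realized genetic variance match the target up to Hardy–Weinberg
  sampling noise. Breeding values are therefore *marker-based*: genomic
  information genuinely carries signal, so the pedBLUP-vs-ssGBLUP
  comparison is informative rather than vacuous. A purely infinitesimal
  mode (pedigree transmission with Mendelian-sampling draws scaled by
  $d_i$) exists for checks where the pedigree model is itself the truth,
  e.g. REML recovery.
* Five traits with heritabilities 0.26–0.56, genetic correlations from a
  published beef-cattle parameter table, phenotypic SDs matching carcass
  phenotype descriptive statistics (e.g. yearling weight SD ≈ 54 kg,
  marbling score SD ≈ 1.6), composite contemporary-group fixed effects
  (8 and 10 levels, level SD half a phenotypic SD) and an age-at-slaughter
  covariate on the carcass traits.
* Info-type labels with the trait-missingness patterns of a testing
  scheme: genotype-only animals (GEN) are drawn from the youngest
  generation, phenotyped classes from older ones; within phenotyped
  classes the yearling-weight-only / all-trait / carcass-only pattern
  fractions follow the relative sizes seen in such programs (0.72 / 0.12 /
  0.16 for phenotype-only animals, 0.38 / 0.62 / 0 for animals with both).
  Default info fractions are OTHER 0.55, PHEN 0.20, PH+GEN 0.17, GEN 0.08
  — preserving the ordering of a real program's subsets (a large
  pedigree-only majority, phenotyped classes next, genotyped-only
  smallest) while keeping each stratum populated at desk scale.

Not emulated: linkage (loci are unlinked, as the methods use no map),
directional selection across generations, genotyping error, and real
LD structure between QTL and markers. Passing tests on these populations
therefore demonstrates the algebra and the directional behaviour of the
methods, not the absolute accuracy levels attainable on any particular
real population.

## Numerical choices

* Blended $G$ and $A_{22}$ are inverted by Cholesky; if factorization
  fails the inverse retries once with a ridge of $10^{-6}$ times the mean
  diagonal, with a message.
* PEV diagonals are clamped at zero when within $10^{-8}$ of it; a
  genuinely negative PEV raises an error, since it indicates an upstream
  numerical fault.
* Filter order in QC is monomorphic → MAF → call rate → animal
  missingness → parentage, with frequencies recomputed downstream of
  animal removal; the order is conventional and makes the filter
  idempotent. A marker at exactly 5% MAF is kept (the criterion is
  "less than").
* Ties in the topological sort keep input order, and all generator
  randomness derives from a single seed, so every artifact regenerates
  bit-identically.

## Problem sizes used by the test suite

The checks run at sizes chosen so the full suite completes in minutes on
one CPU: pedigree-algebra fidelity on fifty random pedigrees of up to 200
animals; MME-vs-GLS agreement on 200-animal two-trait systems; genomic
relationship calibration with 2,000 markers; heritability recovery on
twenty replicates of a 2,000-animal single-trait design (true $h^2 = 0.4$,
estimates within 0.05 of truth on average); a null design of 100 full-sib
families with zero additive variance; and twenty replicates of a
750-animal, 800-marker, five-trait comparison study for the directional
claim — ssGBLUP raises the mean accuracy of genotyped phenotype-less
animals in at least 18 of 20 replicates — plus decile calibration of
predicted against realized accuracy, whose replicate-averaged curve must
agree in rank (Spearman above 0.9). For the replicated comparison the
accuracy metric uses the generator's true additive variances as $V_A$:
both methods share $V_A$, so the comparison is invariant to that choice,
and it avoids re-running a five-trait REML twenty times. The single-shot
analysis workflow under `analysis/` follows the design decision of taking
$V_A$ from pedigree-only REML fits.

## Limitations

Everything is dense at the PEV step, so the practical ceiling is a few
tens of thousands of equations. EM-REML is robust but slow near variance
boundaries. The H-matrix options implemented are the standard
$\tau/\omega$ and blending adjustments; scaling $G$ to $A_{22}$ beyond the
VanRaden denominator (mean-diagonal tuning) is not applied by default, and
neither APY-style sparse approximations nor metafounders are in scope.
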