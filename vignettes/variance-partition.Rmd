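---
title: "Partitioning trait variance into genomic, environmental and gene-by-environment components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance into genomic, environmental and gene-by-environment components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxegreml)
```

## The model

`gxegreml` estimates how much of the variance of a quantitative trait is
attributable to common SNPs, to close-relative sharing beyond what SNPs tag,
to a shared categorical environment such as smoking status, to
genome-by-environment interaction, and to an environment proxy built from
DNA methylation.  The underlying linear mixed model is

$$
y = X\beta + g + k + w + gw + \varepsilon,
$$

with $g \sim N(0, \mathbf{G}\sigma^2_g)$,
$k \sim N(0, \mathbf{K}\sigma^2_k)$, $w \sim N(0, \mathbf{SMK}\sigma^2_w)$,
$gw \sim N(0, \mathbf{GxSmk}\,\sigma^2_{gw})$ and
$\varepsilon \sim N(0, I\sigma^2_e)$.  Any subset of the random effects can
be included; the package's model grid fits the usual combinations (genetics
only, environment as fixed effect, environment as random effect, with and
without interactions, with and without the methylation matrix).

The covariance structures are:

* **G** — genomic relationship matrix from allele-frequency standardized
  dosages, $G_{jk} = \tfrac1m \sum_i (x_{ij}-2p_i)(x_{ik}-2p_i) /
  (2p_i(1-p_i))$, with frequencies estimated in the analysis sample and
  missing dosages mean-imputed per variant (zero contribution on the
  standardized scale, keeping the effective $m$ constant across pairs).
* **K** — the kinship proxy: a copy of **G** with every entry below 0.025
  set to zero, isolating close-relative sharing.  The rule is applied to
  *all* entries including the diagonal; since diagonals sit near 1 this
  never bites in practice, but it keeps the operation a single uniform
  thresholding.
* **SMK** (and **SEX**) — same-category indicator matrices: 1 between
  individuals in the same category, 0 otherwise, 1 on the diagonal.
* **GxSmk**, **GxM**, three-way products — Hadamard (cell-by-cell)
  products of the parent matrices: interaction similarity requires
  similarity on every factor at once, the covariance-matrix expression of
  a reaction-norm model.  The three-way genome-by-smoking-by-sex structure
  is built as $G \circ SMK \circ SEX$; a sex-stratified analysis is the
  alternative the grid also supports.
* **M** — an omics relationship matrix over exposure-associated CpG
  sites, $M = WW'/c$ after iteratively standardizing probes and
  individuals.

CpG sites feeding **M** are chosen by `select_smoking_cpgs()`: association
p below $10^{-7}$ in *both* of two independent EWAS, and heritability
strictly below 40%, so the matrix predominantly captures environmental
rather than genetic variation.

## Phenotype preparation

`prepare_trait()` reproduces the standard preparation chain: (1) adjust
the raw trait for sex, age and age$^2$; (2) mask residuals beyond the mean
± 4 SD; (3) re-adjust the surviving values for sex, age, age$^2$ and
clinic; (4) rank-based inverse normal transform (Blom offset 3/8,
configurable).  Two deliberate choices:

* The ± 4 SD mask acts on *residuals*, before the normalizing transform —
  after an INT no realistic sample can exceed 4 SD, so masking on the
  transformed scale would be vacuous.  Clinic enters only the second
  adjustment, following the order in which the steps are usually
  described.
* The INT output is rescaled to exactly unit sample variance.  Blom
  scores have variance slightly below 1 at finite $n$; rescaling is
  affine and rank-preserving, and makes variance proportions directly
  comparable across traits.

Tied values receive average ranks (deterministic); a fully constant trait
is an error at `prepare_trait()` level.

## REML numerics

`fit_reml()` maximizes the restricted likelihood with average-information
(AI) updates: expectation-maximization steps for the first two iterations,
then damped Newton steps using the AI matrix
$\mathrm{AI}_{ij} = \tfrac12 y'PA_iPA_jPy$.  When an AI step fails to
improve the likelihood — which happens on the near-ridges created by
overlapping structures such as **G** and $G \circ SMK$ — the AI diagonal
is inflated Levenberg-style (factors of 10 from $10^{-4}$) until the step
is an ascent, with a plain EM step as the final fallback.  Convergence is
declared when the likelihood changes by less than `tol` (default
$10^{-6}$), the largest parameter change falls below $10^{-8}$, or the
free-parameter gradient is below $10^{-3}$ with a likelihood change below
$10^{-4}$.

Variance components are constrained non-negative by default via a floor at
$10^{-6}\,\mathrm{var}(y)$ with active-set handling (a floored component
with negative score stays put); `constrain = FALSE` gives unconstrained
estimates.  Standard errors come from the inverse AI matrix at the
optimum; proportions of phenotypic variance and their delta-method SEs use
the full covariance of $\hat\sigma^2$.

The restricted log-likelihood includes its full constant (the Harville
form with the $\log|X'X|$ term), so values are absolute and comparable
across models sharing $y$ and $X$ — which the LRT machinery checks before
comparing.

**Likelihood-ratio tests.**  A variance component under the null sits on
the boundary of its parameter space, so for one tested component the
statistic $2\Delta\ell$ (clipped at zero) is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge
\mathrm{stat})$, with $p = 1$ at zero.  This halves the p-value relative
to a plain $\chi^2_1$; users comparing with tools that use the plain
reference can double it.  For several components dropped at once a
conservative $\chi^2_k$ is used, with a warning.

**Meta-analysis.**  Sub-cohort estimates are pooled by inverse-variance
weighting through `metafor`: DerSimonian–Laird random effects by default
(between-centre heterogeneity is plausible), fixed-effect as an option,
p-values from the normal approximation without a small-$k$ t correction.

## The ORM iteration

`compute_orm()` alternates probe- and individual-standardization until the
largest cell change within a half-sweep is below $10^{-8}$ (cap 100
sweeps).  Standardization uses population ($1/n$) variance denominators in
both directions: with sample ($n-1$) denominators a matrix cannot have
unit-variance rows *and* columns simultaneously — the total sums of
squares $n(c-1)$ and $c(n-1)$ disagree — so the iteration would never
reach a doubly standardized state.  With the common denominator the fixed
point exists, the converged $W$ satisfies both constraints to $10^{-8}$,
and $\mathrm{diag}(WW'/c)$ is exactly 1.

## What the synthetic cohorts emulate

Because the motivating cohorts are access-restricted, the package ships a
generator whose defaults define its calibration conditions:

* **Genotypes**: $m = 5000$ independent SNPs with founder frequencies
  uniform on [0.05, 0.5]; no LD and no realistic frequency spectrum.
  Families are sibships: parents are simulated and discarded, each child
  receiving an allele from each parent with probability half the parental
  dosage, so realized sib relatedness is centred on 0.5 and the
  thresholded **K** matrix has real structure to find.  The default
  cohort is $n = 1000$ with 100 sib pairs.
* **Smoking**: three categories (never/ex/current, probabilities
  0.5/0.3/0.2, roughly a European adult cohort) mapped to dose scores
  0/0.5/1.  A latent individual exposure is the standardized dose plus a
  within-category deviation, mixed so the category explains 50% of the
  exposure variance (`smoking_between_r2`): actual tobacco exposure
  varies within self-report categories, and this is the single mechanism
  that lets methylation outperform self-report below.
* **Methylation**: 62 CpGs (the size of a two-EWAS smoking signature),
  each a mixture of the latent exposure (default $r^2 = 0.3$), a small
  genetic term from 20 causal SNPs (default $h^2 = 0.2 < 0.4$, matching
  the selection rule) and noise.  Exposure loadings carry random signs —
  smoking CpGs are both hyper- and hypo-methylated — which matters
  numerically: a constant-sign loading would be annihilated by the ORM's
  per-individual standardization.
* **Phenotypes**: in the default *covariance-exact* mode every random
  effect is drawn as $\sqrt{f_i}\,L_i z$ with $L_i$ a symmetric square
  root of the corresponding matrix — exactly the estimator's model, so
  recovery experiments isolate estimator behaviour.  The *mechanistic*
  mode instead builds effects from per-SNP effect sizes with
  category-specific deviations, family-block environment and category
  shifts, each term rescaled to its target fraction; it exists to probe
  robustness to the covariance model being only an approximation.  The
  smoking main effect follows the latent exposure by default
  (`smoking_effect = "dose"`); `"categorical"` draws iid per-category
  effects whose covariance is exactly **SMK**, which is what
  covariance-exact recovery of an `Smk` fraction should use.

Default truth is $G = 0.25$, $K = 0.25$, $GxSmk = 0.10$, residual 0.40 —
interaction on the scale reported for adiposity traits, genetics in the
usual range for them.

What passing tests on these cohorts *does not* show: robustness to LD,
to MAF-dependent architecture, to array noise and batch structure in
methylation, or to assortative mating and shared-household effects; the
generator does not contain them.

## Calibration experiments and their sizes

The acceptance suite (mirrored in `scripts/acceptance.R` at reduced size)
checks:

* closed-form equality with ANOVA estimators on a balanced one-way design;
* agreement of the AI-REML optimum with direct numerical maximization of
  the restricted likelihood on random fixtures up to $n = 100$;
* unbiased recovery of all components at the default design over 30
  replicates, with reported SEs within 30% of the empirical SD;
* null calibration of the boundary LRT at $n = 500$ over 300 replicates
  (rejection at $\alpha = 0.05$ expected in [0.03, 0.07]);
* methylation absorption: with a 5% smoking-exposure variance and
  smoking-driven CpGs, adding **M** to a G+K+Smk model removes at least
  80% of the Smk estimate — the package's qualitative reproduction of
  methylation acting as the better exposure measure;
* a negative control with zero interaction, run on a family-rich design
  ($n = 2000$, 500 sibships of four): because the interaction estimate is
  truncated at zero, its mean under the null is roughly $0.4\times$ its
  sampling SD, so the design must be informative enough to push that SD
  near 0.02 before a mean-inflation bound of 0.01 is meaningful.  That
  power consideration, not the estimator, dictates the density of the
  pedigree here.
* bit-level fidelity of the GCTA-dialect GRM files and the dosage text
  format, and the double-standardization property of the ORM;
* exact DerSimonian–Laird arithmetic against a hand-computed worked
  example, including the collapse to fixed-effect pooling when
  $Q \le k-1$.

Problem sizes throughout were chosen as the smallest at which the checked
property is statistically meaningful, which keeps the full suite in the
tens of minutes on a single core.

## Known limitations

* The AI-REML engine is dense ($O(n^3)$ per iteration) and comfortable to
  a few thousand individuals; biobank-scale data needs the randomized or
  streaming tricks of dedicated tools.
* The LRT boundary mixture is exact only for one tested component with
  the others interior; with several components near their floors the test
  is conservative.
* Because components are constrained non-negative, the *mean* of a
  null-truth component estimate is positive — roughly $0.4\times$ its
  sampling SD plus a compensation term with overlapping components — and
  only shrinks towards zero as the design grows.  At desk-scale cohort
  sizes this truncation inflation is visible (about 0.014 for the
  interaction component at the negative-control design); judging absence
  of an effect should therefore rest on the LRT, not on the raw
  constrained estimate.
* `recovery_experiment()` holds genotypes and matrices fixed across
  replicates (the estimator conditions on realized relationships);
  marginal coverage over genotype resampling is not assessed.
* The pipeline assumes phenotype rows and genotype samples are aligned;
  it re-orders nothing silently and errors on id mismatches instead.
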