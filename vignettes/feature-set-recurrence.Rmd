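---
title: "Feature-set recurrence analysis: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-set recurrence analysis: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistics and of the design
choices behind them. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The inferential problem

For common complex disease, genotype-only classifiers sit barely above
chance: effect sizes of common variants are small and different variants
drive the trait in different cases. A single optimized model is therefore a
weak object of inference. `fsrecur` instead treats *selection consistency*
as the statistic. SNPs are grouped into biologically defined feature sets
(FSs) — one per (druggable gene, connected gene) pair — and many independent
stochastic pipeline searches are run, each constrained to begin with a
Feature Set Selector (FSS) that picks exactly one FS. If a particular FS is
selected far more often across runs than chance would allow, that FS carries
signal even when absolute accuracy is modest.

Formally, over $R$ successful runs, the statistic is
$T = \max_F \#\{\text{runs selecting } F\}$, with the best holdout score as
a companion statistic. The null distribution is obtained by permuting the
binary endpoint over the *full* cohort (so case/control totals are
preserved but assignments scramble) before any down-sampling, and repeating
the entire stage — all $R$ runs, with fresh down-sampling and splits — per
permutation. The reported bound is the conservative add-one empirical p,
$p \le (1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\}) / (1 + P)$;
with the small permutation counts this design can afford (the study scale
used 20), the bound cannot dip below $1/(P+1)$ and the package never claims
more. Configuration identity between the observed and null arms is enforced
by a hash over the scientifically relevant settings; a mismatch aborts.

An important property of this null, visible in the package's own acceptance
runs: within one permutation the $R$ runs share the permuted phenotype and
heavily overlapping down-samples, so selection noise is *correlated* across
runs and null recurrence counts run higher than an independent-multinomial
intuition suggests. That is precisely why the null is built by re-running
the whole stage rather than assuming multinomial uniformity. (When
selections are forced uniform and independent — the engine stubbed — the
statistic provably follows the multinomial-maximum distribution; the test
suite checks this by Monte Carlo.)

## Feature-set construction

- **Coordinates.** BED-style 0-based half-open throughout. A SNP at
  position $p$ is the interval $[p, p+1)$; a SNP at an interval's exact end
  coordinate is outside it.
- **Promoter extension.** Each gene body is extended to include 5 kb
  upstream and 1 kb downstream of the TSS, strand-aware (TSS = `start` on
  `+`, `end` on `-`; upstream reversed on `-`), clipped at 0. Whether the
  original pipeline's extension was strand-aware is not documented
  anywhere authoritative, so a strand-agnostic option is provided
  (`strand_aware = FALSE`).
- **Mapping.** A SNP in the extended body is labeled `B`; else, in any of
  the gene's enhancers, `E`; a SNP in both is `B` (a single label per SNP is
  required downstream; body takes precedence). Mixed chromosome naming
  styles (`chr1` vs `1`) raise an error rather than silently failing to
  match.
- **Filters.** QC retains `maf > 0.01` and `info > 0.9` (strict
  inequalities); the functionality filter retains CADD $\ge 10$ *or* GWAVA
  $\ge 0.5$ *or* TraP $\ge 0.459$ (inclusive). A missing score fails its
  condition — score coverage differs between tools in practice — but a SNP
  with all three scores missing is an error, as is a missing MAF or info
  value. The two filters commute; the suite asserts this.
- **LD pruning.** Greedy scan in genomic-position order: a SNP is retained
  iff its squared Pearson dosage correlation with every already-retained SNP
  is $\le r^2_{\max}$ (0.8 by default; the GWAS-loci baseline analysis uses
  0.6 — a parameter, not a second code path). The scan order is a parameter
  because the reference tool's internal order is undocumented; given the
  order the result is deterministic. Zero-variance columns have undefined
  correlation; they are treated as uncorrelated, retained, and flagged.
- **Assembly.** One FS per (druggable, connected) pair: the union of both
  genes' retained SNPs, deduplicated, position-ordered. By construction any
  two FSs of the same druggable gene share all of that gene's SNPs.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without
access-controlled biobank data. It emulates:

- **Dosages.** Biallelic, in $[0,2]$, as sums of two haplotypes, one draw
  per allele with the SNP's MAF. MAFs default to Uniform(0.05, 0.5) in
  annotation fixtures; imputation info to Uniform(0.92, 1), so QC passes by
  construction and the functionality filter can be exercised independently
  through `pass_fraction`.
- **LD.** A haplotype-copy chain within blocks: with probability
  `ld_rho` an allele copies the previous SNP's allele on the same
  haplotype, else it is drawn fresh. This gives tunable adjacent-pair
  $r^2 \approx \rho^2$ when MAFs are comparable. Known limitation: with
  heterogeneous MAFs inside a block, marginal MAFs drift toward the
  upstream SNP's MAF; moment checks therefore use `ld_rho = 0` or
  equal-MAF blocks.
- **Population structure.** With $K$ subpopulations, per-SNP allele
  frequencies are shifted by equally spaced offsets spanning
  `subpop_maf_shift` (default 0.2, a deliberately strong, ancestry-like
  separation) in a random per-SNP direction. The leading PCs of the
  standardized dosage matrix (truncated SVD, mimicking biobank-supplied
  PCs) then separate the subpopulations; `genotype_pcs()` supplies them as
  covariates.
- **Phenotype.** Each sample draws a latent subgroup; its case probability
  is `plogis(baseline + sum(beta * dosage) over the subgroup's causal set +
  covariate terms)`. Disjoint causal sets across subgroups emulate genetic
  heterogeneity. Covariate effects default to weak age (0.01 per year,
  centered at 57) and sex (0.1) effects, zero array and PC effects —
  small nuisance structure without dominating the genetics. Subgroup labels
  and true case probabilities are kept as attributes for validation and
  never exposed to the modelling stages.
- **Bayes accuracy.** `bayes_accuracy()` returns the genotype-only ceiling
  $\mathbb{E}[\max(p, 1-p)]$ with $p$ the subgroup-marginal case
  probability. Covariate terms are excluded (the signature takes only the
  model and the genotypes), so comparisons against it set covariate effects
  to zero. It anchors the planted-signal tests: the PRS baseline with
  generative weights must reach it to within sampling error.

What the generator does *not* emulate — realistic allele-frequency spectra,
long-range LD, imputation error, phased haplotypes, X chromosome,
case-covariate confounding beyond linear PC structure — bounds what passing
tests show: they validate the *procedure* (selection, recurrence,
calibration, leakage-freedom, attribution), not performance claims on real
cohorts.

## One stage of the search procedure

Per run: (1) down-sample controls to the case count (all cases kept);
(2) randomly split into train / holdout-1 / holdout-2 with fractions
(0.75, 0.13, 0.12) — holdout sizes are `floor(f * n)`, remainder to train,
so at the study's cohort size (19,134 cases, balanced to 38,268) the
holdouts are 4,974 and 4,592; (3) optionally residual-adjust ("resAdj") the
outcome on age + sex + PC1..10 and every feature on array + PC1..10, with
ordinary-least-squares coefficients fitted on *training rows only* and
applied as residuals everywhere — adjusting the outcome turns the problem
into regression, scored by the coefficient of determination; (4) run the
evolutionary pipeline search on the training part with 5-fold CV;
(5) score the best pipeline on holdout-1 (stage 1) or holdout-2 (stage 2,
whose feature matrix is restricted to the stage-1 winner's SNPs and whose
template drops the FSS step). Per-run failures are caught and recorded, not
propagated; the recurrence summary counts successful runs.

The search engine is deliberately a *reduced* automated-ML search, not a
re-implementation of any particular framework: the findings it supports
depend on feature-set selection consistency, not on a specific operator
library. Templates are fixed ((FSS →) Transformer → Estimator); the
operator pool is small (identity / standardize / variance-threshold /
percentile-selector transformers; logistic-or-OLS, ridge, random forest,
gradient-boosted-tree estimators with tiny grids); evolution is tournament
selection of size 2, slot-swap crossover, single-slot mutation, elitism of
one. CV scores are cached per configuration; ties in best CV score break by
earliest creation order; everything is deterministic per seed. Default
budget at study scale is population 100 x 100 generations with an optional
wall-clock limit; test configurations shrink to populations of 4-20 and 2-6
generations, which the tiny configuration space (often ~20 distinct
pipelines) makes sufficient.

Seeding follows one documented counter scheme (`derive_seed()`): every
down-sampling, split, fold assignment, search, permutation and SHAP call
derives its seed from the base seed and its position in the workflow. No
global RNG state crosses stages, and reruns are bit-identical.

## Explanation stack

- **Well-predicted cases.** Classification: cases with predicted
  probability above 0.5. Regression (resAdj): cases in the bottom quartile
  of absolute error among cases only; the cutoff is the 25% order statistic
  and boundary ties are all included, so the count can exceed $\lceil n/4
  \rceil$.
- **Kernel SHAP.** Model-agnostic Shapley estimation by weighted least
  squares over coalitions, absent features imputed from a weighted k-means
  background whose centroid coordinates are snapped to observed feature
  values (keeping dosage-like features on their support {0, 1, 2, ...}).
  With all $2^M - 2$ non-trivial coalitions enumerated (the default for the
  FS-sized problems here, $M \lesssim 12$) the solution equals the exact
  Shapley value; the suite verifies agreement with $2^M$ enumeration to
  1e-6. The local-accuracy constraint (attributions plus base value equal
  the model output) is imposed by elimination, so it holds to numerical
  precision in both full and sampled modes. Sampled mode draws coalitions
  in complementary pairs with size probabilities proportional to the
  aggregated kernel mass, always including all singleton and leave-one-out
  coalitions so every feature is identifiable.
- **Cluster count selection.** The Dunn index (minimum inter-cluster
  distance over maximum intra-cluster diameter; +Inf flagged when all
  diameters vanish) is computed for k-means fits across a k range; the
  maximizing k wins, ties to the smallest. Because an analyst inspecting a
  force plot may prefer a different k (the study fixed 4 and 6 clusters
  this way), `cluster_cases_by_shap()` takes a `k_override`, and the full
  Dunn-versus-k report is always returned for inspection. Background sizes
  use the same criterion over k = 30..100 at study scale; toy
  configurations shrink the range with the data.
- **Rankings and export.** Within each cluster, features rank by mean
  absolute SHAP value (ties by feature id); cross-cluster displays use the
  union of per-cluster top-m features. `export_force_matrix()` writes the
  long-format table behind a stacked force plot, with a case ordering from
  deterministic nearest-neighbour seriation (identical rows adjacent) or
  supplied by the caller.

## Numerical conventions and degenerate inputs

- Accuracy thresholds probabilities at 0.5 strictly (`> 0.5` is a case).
- $R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ from the evaluation fold's
  own mean; a zero-variance fold yields NA and the configuration scores as
  failed.
- Rank-deficient covariate matrices in the adjuster fall back to the
  Moore-Penrose pseudoinverse with a warning.
- Transformers never emit zero features (variance thresholding keeps the
  highest-variance column if nothing passes); ridge fits pad a zero column
  when only one feature remains (the backend requires two).
- The phenotype permutation redraws if it reproduces the original
  assignment exactly, so the identity permutation cannot occur.
- Split fractions must sum to 1 within 1e-9; subgroup fractions within
  1e-12.

## Problem sizes used by the tests and acceptance script

The suite runs planted-signal recurrence at n = 2,000 samples, 10 feature
sets, 3 causal SNPs of effect 1.2 (genotype-only Bayes accuracy ~0.72),
20 observed runs against 5 permutations x 20 runs; null calibration with
200 stubbed replicates against 20,000 Monte-Carlo draws; the PRS/engine
comparison at n = 20,000 and 20 SNPs; SHAP oracles at M = 2..8 over 20
random models; Dunn oracles on 50 random instances of up to 100 points.
These sizes were chosen as the smallest at which each check is
statistically decisive; all thresholds and seeds are fixed in the test
sources.

## Known limitations

- The evolutionary engine's mutation and selection parameters are its own;
  no claim is made that they match any external AutoML framework's
  internals, and its accuracy on real cohorts is untested here.
- The recurrence permutation null is not analytic; with few permutations
  the p bound is coarse by design.
- resAdj stages have no valid phenotype-permutation null: permuting the
  outcome would break the outcome-covariate relationship that the
  adjustment itself models (PCs are confounders adjusted on both sides),
  so the package does not offer one.
- Kernel SHAP cost grows as $2^M$ in full mode; beyond ~15 features use
  sampled mode, whose attribution error (unlike its local accuracy) is not
  bounded a priori.
- The LD model's marginal-MAF drift inside heterogeneous blocks, and the
  absence of realistic frequency spectra, mean simulated cohorts are
  structurally simpler than biobank data.
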