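---
title: "Balanced top-line selection: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced top-line selection: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(topsel)
```

## The selection problem

A breeding program phenotypes a panel of lines (adjusted means, BLUEs,
one value per line within an environment and trait), genotypes them at
genome-wide SNPs, and must decide which candidates to advance. With
`direction = "top"` the targets are lines whose trait value exceeds the
empirical τ-quantile Y~τ~ of the training responses (τ = 0.8 by
default, i.e. the top 20%); `direction = "bottom"` mirrors everything
through the 1 − τ quantile for traits where low is good. Viewed as a
binary classification — is this line a top line? — the quality of a
selector is measured by sensitivity (top lines found), specificity
(non-top lines excluded), precision, F1 and Cohen's κ, not by squared
prediction error.

## Models

**Linear GBLUP.** `fit_gblup()` fits
Y~i~ = μ + g~i~ + ε~i~ with g ~ N(0, σ²~g~ G) and
ε~i~ ~ N(0, σ²). G is the VanRaden relationship matrix
(`compute_grm()`): observed-frequency centering, denominator
2 Σ p~j~(1 − p~j~) over polymorphic markers, frequencies estimated from
all lines together so one G serves a whole cross-validation. Models are
fitted per environment and trait; environment effects are assumed
removed upstream in the BLUEs, and no genotype-by-environment
covariance is modeled.

**Probit threshold GBLUP.** `fit_probit()` fits
P(Y~b,i~ = 1 | g~i~) = Φ(β₀ + g~i~) through latent liabilities
l~i~ = β₀ + g~i~ + ε~i~ with the residual liability variance fixed at
1 (the scale is not identifiable from binary data) and a flat prior on
β₀. Liabilities are drawn from truncated normals: positive iff the
observed label is 1.

Both samplers work in the eigenbasis of the training block of G,
G~tt~ = U D Uᵀ: the rotated effects a = Uᵀg have independent normal
conditionals, so one eigendecomposition per fit buys fully vectorized
O(n) updates. Masked (test) lines contribute no likelihood; their
genetic values are projected through
E[g~test~ | g~train~] = G~test,train~ G~tt~^−1^ g~train~, which gives
the same posterior for g as response-imputation schemes. Probit
predictive probabilities integrate the conditional prediction variance
v~i~ analytically, averaging Φ((β₀ + m~i~)/√(1 + v~i~)) over kept
draws — same expectation as sampling g~test~, less Monte-Carlo noise.

**Priors and defaults.** Scaled-inverse-chi-squared priors on both
variance components, df = 5, scales splitting the training-response
variance 50/50 between genetic and residual (the genetic scale divided
by the mean training diagonal of G) — the convention of standard
genomic-prediction Gibbs samplers. Chain defaults are
`n_iter = 6000, burn_in = 1000, thin = 5`; small-n GBLUP mixes fast,
and every experiment below states the (shorter) chains it used. Seeds
are mandatory everywhere — settings, CV plans, simulations — because
silent default seeds make MCMC benchmarks irreproducible.

## The five selectors

| model | fit | rule |
|-------|-----|------|
| RC | GBLUP | select the k best-predicted test lines, k = observed top count |
| R  | GBLUP | Ŷ~i~ > Y~τ~ |
| RO | GBLUP | Ŷ~i~ > Y~o~, Y~o~ tuned |
| B  | probit | p̂~i~ > 0.5 |
| BO | probit | p̂~i~ > τ₀, τ₀ tuned |

All comparisons are strict; a score exactly at the threshold is *not*
selected (ties labeled 0). RC's equal-count construction forces
FP = FN on every fold, hence sensitivity = precision — asserted exactly
in the tests. Ties at RC's rank k are broken by line id
(lexicographic), making the rule deterministic.

**Threshold tuning (RO/BO).** Within each outer-training set, a 10-fold
inner split is made. Per inner fold the candidate cuts are the
midpoints of adjacent sorted unique validation scores plus one cut
below the minimum and one above the maximum (probability scale:
midpoints plus the default 0.5) — any threshold between two consecutive
scores yields the same confusion matrix as their midpoint, so this set
covers every achievable confusion matrix; a fixed grid would not. The
per-fold optimum minimizes (Sensitivity − Specificity)²; among ties the
candidate closest to the base threshold (Y~τ~, or 0.5) wins, i.e.
minimal deviation from the default rule. The final threshold is the
mean of the per-fold optima. Inner folds with a single label class
carry no sensitivity/specificity information and are skipped (with a
message); if every fold is degenerate the base rule is returned with a
warning. By construction the tuned per-fold objective never exceeds the
base rule's objective on the same folds.

`adjusted_predictions()` expresses the tuned rule on the familiar
scale: Ŷ\* = Ŷ·(Y~τ~/Y~o~) classified against Y~τ~ equals Ŷ against
Y~o~ when the ratio is positive; with opposite signs the equivalence
fails, a warning is emitted, and the direct Y~o~ rule stays
authoritative.

**O vs S.** The O method refits the model for each inner fold (10 extra
fits per outer fold). The Simple method fits once per outer fold and
partitions the fit's *in-sample* fitted values into the 10 tuning
folds (`simple_tuning_scores()`). In-sample fitted values are less
shrunken than out-of-sample predictions, so S-tuned thresholds are
biased upward relative to O-tuned ones — the price of the ~10× speedup.
Tuning on test predictions instead would leak test labels into the
threshold and was rejected.

## Evaluation harness

`run_nested_cv()` runs the nested 5×10 cross-validation for one
(environment, trait) slice: per outer fold, Y~τ~ is computed from the
outer-training responses, labels are binarized with it, the needed
models are fitted with the test lines masked (RC/R/RO share one linear
fit; B/BO share one probit fit), thresholds are tuned on inner splits
of the training set only, and the test lines are classified. Test
labels never influence any threshold; `holdout_selection()` exposes the
single-split engine so an audit can corrupt the test responses and
verify bit-identical thresholds. `benchmark_dataset()` maps the harness
over every environment × trait slice, and `aggregate_metrics()`
collapses fold → environment×trait → dataset → across-data, with the
dataset-level SE taken across environment×trait means (sd/√n~combos~).
Degenerate metric cells (0/0, e.g. sensitivity with no positives, or κ
with P~e~ = 1) are flagged `NA` and excluded from means with a reported
count; coercing them to 0 would bias dataset summaries downward.
`relative_efficiency()` reports m~y~/m~z~ as a percentage improvement,
or as a decrease (1 − RE)·100 when quantifying how far a weaker method
falls short; percentages are rounded to two decimals.

## Synthetic data

`simulate_markers()` draws allele frequencies uniformly from
`maf_range` (default 0.05–0.5) and dosages as Binomial(2, p) per line —
Hardy–Weinberg proportions, no linkage disequilibrium, no population
structure. `simulate_phenotypes()` picks `n_qtl` causal markers,
standard-normal additive effects, and rescales the Gaussian noise so
the realized in-sample variance ratio equals the target h² *exactly*,
giving recovery tests a sharp truth value instead of a noisy one.

What this emulates: an additive polygenic trait measured on a panel of
unrelated-to-weakly-related lines, the regime the selectors assume.
What it does not: LD structure, family structure, dominance/epistasis,
genotype×environment correlation (slices are simulated independently),
and non-Gaussian error. Tests passing on these simulations therefore
validate the *methods and their implementation* — the balancing
behavior, the invariants, the samplers — not field performance on any
real population; relationship structure in real panels can make every
metric better or worse.

Preset bundles: `tiny` (60 lines × 200 markers, one slice; an
end-to-end pipeline in seconds) and `paper_shape` (1000 × 4085 × 11
environments × 4 traits, the shape of a typical public maize
genomic-selection dataset).

## Validation experiments and problem sizes

The test suite validates the pipeline at these sizes, chosen to make
each check sharp while keeping a full run in minutes:

- metric formulas against a brute-force re-evaluation on 1000 random
  confusion matrices (exact agreement);
- Gibbs GBLUP vs the closed-form BLUP oracle at fixed variance
  components: n = 100, 25 masked lines, 3 seeds, correlation > 0.99;
- heritability recovery: 10 replicates × h² ∈ {0.3, 0.7}, n = 300,
  p = 500, mean estimate within ±0.15;
- the balance property: 20 replicates (n = 300, h² = 0.5, τ = 0.8),
  full nested 5×10 CV with per-inner-fold refits and short chains
  (600 iterations, 200 burn-in): mean test-set |sensitivity −
  specificity| drops from ≈0.96 (R) and ≈0.99 (B) to ≈0.13 (RO, BO);
- a leakage audit corrupting test labels and asserting unchanged
  thresholds.

Reproducing the published multi-dataset maize/soybean benchmark values
themselves requires the external genotype/phenotype data and long
chains; the harness runs that experiment when such data are supplied,
and the bundled `reported_benchmark_means()` table carries the
published summary means so the relative-efficiency worked examples are
reproducible by arithmetic.

## Numerical choices and degenerate inputs

- G is ridge-stabilized (`stabilize_grm()`, default 1e-6) before
  factorization; finite panels and duplicated lines make G numerically
  singular. Eigencomponents below 1e-8 of the largest are dropped.
- Missing dosages are mean-imputed per marker; an all-missing marker is
  an error. Missing phenotypes are flagged and excluded from training,
  never silently dropped from files.
- Monomorphic markers contribute zero to both numerator and denominator
  of G and are excluded from the denominator; an all-monomorphic panel
  is an error.
- A constant training response gives a guarded prior scale (the
  sampler shrinks all genetic effects to ~0 and predicts the constant).
- Truncated-normal liability draws clamp the inverse-CDF argument to
  [1e-12, 1 − 1e-12] to stay finite at extreme linear predictors.
- Single-class binarized training labels abort the probit fit — the
  truncation is degenerate and no threshold can be balanced.

## Limitations

Single-trait, single-environment predictor by design (slices are
analyzed independently); no BayesA/B/Lasso-type marker priors; no
pedigree or non-additive kernels; quantile labeling assumes enough
training lines that the τ-quantile is stable (at least 5 enforced, many
more advisable). The S variants trade threshold quality for speed, most
visibly in specificity.
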