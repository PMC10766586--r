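---
title: "taxassoc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{taxassoc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the ensemble is defined, which choices were open
and how they were resolved, and what the synthetic benchmark does and does
not demonstrate. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

The input is a samples × features matrix of non-negative counts (ASVs/OTUs,
or counts collapsed at a higher taxonomic rank) and one continuous value per
sample, e.g. an ED50 thermal-tolerance estimate in °C. The question is which
features are robustly associated with the variable, and in which direction.

Count tables from amplicon sequencing are compositional: only relative
information survives library-size normalization, so any analysis is
transform-dependent. Rather than committing to one transform and one model,
the ensemble runs eight paths — {l1, clr} × {lasso, adaptive lasso, CFS,
full feature set} — and aggregates them. The two transforms probe
mathematically different versions of the association (proportions vs
log-ratios); the three selectors span penalized-linear and correlation-based
viewpoints; the full-set path lets the random forest see everything. A
random-forest regressor is the common downstream model because it captures
monotone and non-linear relationships that a purely linear selector would
miss, at sample sizes where anything more flexible would overfit.

Per-feature evidence is aggregated as

    score_k = ( Σ_t importance_kt · max(R²_t, 0) ) / 8 · m_k / 8

with `importance_kt` the feature's impurity importance in path t normalized
to sum to 1 over features (0 for features the path did not choose), `R²_t`
the path's pooled leave-one-out R², and `m_k` the number of paths (0–8) that
chose the feature. The three factors reward, respectively, within-model
relevance, trust in models that actually predict, and agreement across
methodologically different routes.

Two readings of this aggregation were possible where the denominator
placement is concerned; the adopted reading (mean over the 8 paths of
importance·R², scaled by m_k/8) is the one consistent with m_k being bounded
by 8 and with a score bounded in [0, 1], which the report relies on.

Three further interpretation decisions, recorded here because the
alternatives were defensible:

* **Negative R² is clamped to 0 inside the score.** Pooled LOOCV R² is
  negative whenever a path predicts worse than the target mean; an unclamped
  score could then be pulled negative by a bad path's importances. Clamping
  means non-predictive paths contribute nothing (they still count toward
  m_k).
* **"Chosen" for the two full-set paths means importance > 0.** The full
  paths select nothing, so without this reading every feature would get
  m_k ≥ 2 for free and the robustness term would lose its meaning.
* **Ties in the ranking** are broken by larger m_k, then lexicographic
  feature id, so equal-scoring features always print in the same order and
  repeat runs are comparable rank-by-rank.

## Validation scheme

With n ≈ 20–30 samples, a held-out test set is unaffordable, so every path
is validated by leave-one-out cross-validation: each sample is predicted
once by a model trained on the other n−1. Selectors run *inside* every fold,
on the training rows only — selection is part of the model being validated,
and running it once on all data would leak the held-out sample into its own
prediction. The n held-out predictions are pooled into one R² (about the
mean of the observed targets) and one MSE; per-fold R² is undefined for a
single test point, so pooling is forced, and the pooled R² may legitimately
be negative. A fold whose selector returns an empty set falls back to the
training-mean constant predictor rather than aborting, keeping all 8 paths
comparable. Both transforms are strictly row-local (each sample's
transformed values depend only on that sample's counts), so transforming
before or within folds is mathematically identical; transforms are computed
once.

Whole-data refits — run after validation, on all n samples — supply what
LOOCV cannot: a single selected set per path, normalized importances, and
for the penalized paths signed coefficients plus intercept on the original
predictor scale, which give the direction of association.

## Tunable parameters

* `pseudocount` (default 1.0, added to raw counts before clr). Zeros are
  endemic in count tables and the log-ratio needs positive entries. An
  additive constant on counts is the simplest defensible replacement; its
  value is recorded in the run log. Results for rare taxa are sensitive to
  it; abundant taxa are not.
* `n_trees` (default 500) and `mtry = p/3` (the regression convention),
  unlimited depth, fixed seed. Forests at these sizes cost little and
  importance estimates stabilize with tree count.
* `gamma` (default 1) and `epsilon` (1e-6) for the adaptive lasso weights
  `w_j = (|β̂_j| + ε)^gamma`. The initial estimator is ridge regression
  (penalty by internal CV), not OLS, because p ≫ n makes OLS ill-posed.
  `gamma = 0` reduces the method exactly to the plain lasso, which the test
  suite asserts.
* Penalty strengths for lasso/ridge stages are chosen by internal 5-fold CV
  over glmnet's log-spaced path, on the training data of the current fold
  only — nesting inside the outer LOOCV prevents leakage. No tuning scheme
  was prescribed for the original ensemble; this is the standard one.
* CFS uses absolute Pearson correlations and forward best-first search with
  a stall limit of 5 consecutive non-improving expansions (`cfs_stall`),
  the canonical configuration of the method it implements; expansion ties
  break lexicographically for determinism.

One implementation subtlety worth recording: adaptive-lasso weights act by
rescaling predictor columns, and glmnet's internal standardization would
silently undo exactly that rescaling. Both penalized selectors therefore
standardize in-house, call glmnet with `standardize = FALSE`, and
back-transform coefficients to the original scale. Zero-variance predictors
are mapped to all-zero columns, so they can never be selected; undefined
correlations (constant features) are treated as 0 in CFS.

## The synthetic benchmark

`generate_synthetic()` emulates the data regime the ensemble targets:
defaults of 28 samples × 150 features with 8 planted features, log-normal
latent abundances, structural zeros at rate 0.5 among background features,
multinomial counts at a Poisson library size (mean 10⁴), and a toy
family-level taxonomy.

The planted features model a trait-associated consortium: they share a
latent per-sample community factor (unit loading, sign per family) on the
log-abundance scale, on top of unit independent log-scale noise, and are
drawn as prevalent, moderately abundant taxa. Both choices are deliberate.
Co-variation is how trait-associated taxa behave in real communities
(consortia respond together), and it is what makes an association of this
size detectable at all at n = 28: eight mutually independent contributors
would each be marginally invisible (|r| ≤ 1/√8 of the signal), and no
method could recover them at this sample size. Prevalence reflects that an
association study can only see taxa that are actually observed. The target
is the signed sum of the planted features' standardized clr abundances plus
Gaussian noise scaled so that `sd(signal)/sd(noise) = effect_size`; the
default effect 2 therefore corresponds to a planted R² of 0.8, a strong but
not unrealistic community signal. Effects are planted on the clr scale so
that neither transform branch is privileged.

What passing tests on these data show: the pipeline recovers planted,
prevalent, co-varying signals at realistic n/p, its ranking is stable under
forest stochasticity, and its performance degrades (never improves) as
samples are removed. What they do not show: behavior under rare-taxon
signals, single-taxon effects at small n, non-monotone associations,
confounded designs, or real phylogenetic correlation structure — the
generator makes no attempt to mimic real taxon abundance distributions
beyond sparsity and overdispersion.

## Robustness protocols

`repeat_run_stability()` re-runs the pipeline varying only the forest seed
and reports pairwise Pearson correlations of score vectors and Spearman
correlations of rank vectors (all features, and the top-k set by mean
score). Selector outputs do not depend on the forest seed, so they are
computed once and shared — a pure caching optimization with identical
results. `jackknife_sensitivity()` subsamples without replacement at given
sizes and tracks the best path's pooled R².

Problem sizes used by the shipped tests were chosen to exercise the claims
at meaningful scale while keeping the suite quick to run: the stability and
jackknife protocols use the generator's default 28 × 150 dataset with 10
repeats / 10 replicates per size (sizes 24 and 8, 300–500 trees); recovery
uses five generator seeds at the default effect; the null-enrichment check
uses eight 24 × 40 null datasets. The acceptance script uses the default
dataset, 10 repeats, 500 trees.

## Known limitations

* Scores are relative rankings, not significance statements; no p-values
  are attached, and associations are not causal claims.
* The clr branch depends on the pseudocount for rare taxa; conclusions
  about low-abundance features should be checked at more than one value.
* LOOCV R² at n ≈ 20–30 has high variance; the jackknife protocol exists
  precisely to show how fast confidence degrades below ~20 samples, and
  runs below that size warrant the warning they trigger.
* CFS best-first with a finite stall limit is a heuristic; it provably
  matches exhaustive search only at small p (asserted for p ≤ 8 in the
  tests).
* Rank positions of features with near-tied scores are not stable across
  forest seeds: impurity importance is a noisy estimator, and when several
  features (typically the weakest recovered signals and chance-correlated
  background taxa) score within a few percent of each other at the tail of
  the top set, their relative order reshuffles between repeat runs even
  though score vectors correlate near 1. Interpret close scores as a group,
  not by their printed order.
* The two-tier workflow conditions tier 2 on tier-1 winners; its child-level
  scores are conditional on that filter and not corrected for the selection.
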