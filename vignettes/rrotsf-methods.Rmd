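---
title: "Random rotation survival forests: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random rotation survival forests: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrotsf)
```

## The problem

Gene-expression survival studies routinely have a few hundred subjects and
tens of thousands of covariates, with a third or more of the follow-up times
right-censored. Classical rotation forests — which rotate the full covariate
space by PCA before growing each tree — are attractive because keeping *all*
principal components preserves information while the per-member rotation
injects diversity, but a full `p x p` eigendecomposition is hopeless at
`p ~ 10^4`. This package implements the random rotation survival forest: each
ensemble member first draws a small random subspace, so every
eigendecomposition is at most `r x r` with `r = ceiling(sqrt(p))`, and the
base learners are survival trees rather than classifiers.

## The ensemble construction

For member `i` of the ensemble, with training data `(t_q, d_q, X_q)`,
`q = 1..n`:

1. **Random subspace.** Draw `r` of the `p` covariates uniformly without
   replacement (default `r = ceiling(sqrt(p))`).
2. **Bootstrap.** Draw `n` subjects with replacement from the subspace data.
3. **Partition.** Randomly split the `r` subspace positions into
   `k = floor(r / M)` subsets of exactly `M` positions (default `M = 2`);
   the `r mod M` leftovers form the *remainder set* RV.
4. **Blockwise PCA.** For each subset, compute the PCA loading matrix of the
   bootstrap rows restricted to those columns, after mean-centering and with
   *all* components retained, so each block loading is orthogonal and the
   within-block variance is exactly preserved. Assemble the loadings into an
   `r x r` rotation matrix laid out in subspace order; rows and columns at
   RV positions are set exactly to zero, which injects a little extra
   randomness member-to-member.
5. **Base learner.** Grow a survival tree on the rotated bootstrap rows.

Prediction aggregates the members' leaf Nelson–Aalen cumulative hazard
functions (CHFs) on the shared grid of distinct training event times by a
pointwise mean; the *mortality* risk score of a subject is the sum of its
ensemble CHF over that grid, so higher mortality means shorter predicted
survival.

### Interpreting the remainder set

Two readings of RV are possible: the `p - r` covariates outside the
subspace, or the `r mod M` subspace positions left over by the partition. We
use the latter — it is the only reading under which the rotated design has
`r` columns and the member's tree sees a consistent feature space; the
`p - r` unselected covariates are simply not part of the member at all.
Zeroing RV's rotation coefficients and excluding those variables are
observationally equivalent for tree learners (a constant zero column is
never split on); we zero them, which keeps the rotation matrix square and
the bookkeeping uniform.

### Order of the random draws

The subspace is drawn first, then the bootstrap, then the partition. Only
the relative order of subspace and bootstrap could matter statistically, and
only through which covariates the PCA sees; we follow the construction order
listed above, and each member consumes its own RNG substream (see
*Reproducibility*).

## The survival tree

Node splits maximise the two-sample log-rank chi-square statistic

$$
\chi^2 = \frac{\left(\sum_j d_{1j} - Y_{1j} d_j / Y_j\right)^2}
  {\sum_j d_j \frac{Y_{1j}}{Y_j}\left(1 - \frac{Y_{1j}}{Y_j}\right)
  \frac{Y_j - d_j}{Y_j - 1}},
$$

summed over the node's distinct event times `j`, where `Y` counts subjects
at risk and `d` events, and the `1` subscript restricts to the proposed left
child. Every rotated feature is a candidate at every node (randomness is
already supplied by subspace, bootstrap and rotation, so no per-node feature
subsampling is added), and every midpoint between consecutive distinct
observed values is a candidate threshold. Stopping rules, all tunable:

* `min_node_size = 15` — no child may fall below this many subjects; the
  usual survival-forest terminal size, large enough for a stable leaf CHF.
* `min_events_to_split = 3` — a node with fewer events becomes a leaf.
* `max_depth = Inf` — depth is already bounded by the size rules.
* a node whose best statistic is 0 becomes a leaf.

Each leaf stores the Nelson–Aalen estimator of its own training rows:
increments `d(t)/Y(t)` at each distinct event time, censored times shrinking
later risk sets only. Leaf CHFs are step functions, right-continuous and 0
before their first jump, and are re-evaluated on the ensemble's shared grid
at aggregation time.

### Determinism and tie-breaking

Ties are resolved by fixed rules so a refit is bit-identical: among
equal-statistic splits the lowest feature index wins, then the smallest
threshold (the split search visits candidates in exactly that order and only
a strictly larger statistic replaces the incumbent); routing sends values
equal to a threshold left; eigenvector signs are fixed by making each
column's largest-magnitude entry positive. A block whose bootstrap columns
are all constant keeps identity loadings rather than failing — constant
columns are never chosen by the split search, so this only keeps training
going on degenerate inputs. The split search itself is compiled (C++), as is
usual for survival forests; the exported `logrank_statistic()` is the
reference implementation it is tested against.

## Risk score and concordance

The concordance index follows Harrell's permissible-pair rules: a pair is
valid when the smaller observed time is an event (pairs with equal times are
valid only when exactly one is an event, that subject counting as the
earlier failure); a valid pair scores 1 when the earlier failure has the
higher predicted risk, 0.5 on tied predictions, 0 otherwise. All-tied
predictions therefore score exactly 0.5 and a perfect anti-ordering exactly
1. We deliberately use the permissible-pair rule rather than enumerating
*all* pairs of observed times, since ordering a censored pair below the
censoring time is not determinable; the README states this contract too.

Model comparison escalates exactly as the evaluation protocol prescribes:
mean C-index per model per dataset from 5x2 cross-validation (five
independent half/half splits, each half once training and once test, all
models sharing the splits); within-run ranks (rank 1 = best, ties averaged)
pooled across datasets; the classical Friedman chi-square on the pooled rank
matrix (runs are the blocks — pooling the 10 runs per dataset rather than
dataset means keeps N large enough for the asymptotics); the Nemenyi
studentized-range post-hoc on mean-rank differences; and a two-sample
Wilcoxon rank-sum test (exact for two small tie-free samples, otherwise
normal approximation with tie-corrected variance) for pairs the Nemenyi test
leaves unresolved.

## The synthetic generator

`simulate_survival_data()` emulates the structure of the high-dimensional
benchmark studies this method targets: `n` in the low hundreds to low
thousands, `p` up to tens of thousands, a small informative subset, and
independent censoring at a controlled rate.

* Covariates are standard normal with equicorrelation `correlation`
  (default 0) through a single shared factor — `O(np)` cost even at
  `p ~ 10^4`.
* Event times come from a Weibull proportional-hazards model by inverse-CDF
  sampling (default shape 1.5, scale 1 — a gently increasing hazard;
  because the C-index is rank-based, the baseline shape does not affect
  discrimination, only the time scale).
* Censoring is exponential and independent of the covariates; its rate is
  calibrated by root-finding *on the realized sample* so the achieved
  censoring fraction lands within 0.05 of `target_censoring` (default 0.3,
  typical of the benchmark cohorts).

What it does **not** emulate: heavy-tailed and bimodal gene-expression
marginals, block/pathway correlation structure, covariate-dependent
censoring, or clinical covariates mixed with expression features. Tests that
pass on this generator therefore demonstrate the estimators' correctness and
the pipeline's statistical calibration, not state-of-the-art accuracy on
real cohorts.

## Reproducibility

A single master seed drives everything. The fitter draws one sub-seed per
member up front, so member `i` is a pure function of (data, hyperparameters,
sub-seed `i`); a forest with `n_trees = k` is a prefix of one with
`n_trees = k + 1` at the same seed, refits are `identical()`, and a model
written with `write_rrotsf()` and reloaded predicts bit-identically. The CV
harness similarly derives per-replication and per-fit seeds from its own
seed, and shares splits across learners. Helpers that consume randomness
save and restore the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the estimators against brute-force oracles at small `n`
(pair enumeration up to `n = 50`, eigendecompositions up to `p = 10`,
exhaustive Wilcoxon enumeration up to 13 pooled observations) and the whole
pipeline at `n = 300, p = 500` with 100 trees — large enough that the
subspace rule (`r = 23`) and the rotation machinery are genuinely exercised,
small enough to run routinely. Signal-recovery checks use 10 informative
covariates at log-hazard effect 1 and ~30% censoring; null-calibration
checks use the same shapes with all effects zero. The Friedman type-I-error
simulation uses 1000 null replicates of a 10-run, 4-model grid.

## Known limitations

* No covariate-importance scoring: the per-member bootstrap would support a
  permutation importance, but no principled definition is fixed for rotated
  subspace members, so none is offered rather than an ad-hoc one.
* No handling of missing values (rows must be complete), interval censoring,
  left truncation or competing risks.
* Sparse independent signal at large `p` is intrinsically hard for
  subspace-based ensembles: with `r = ceiling(sqrt(p))`, the chance that a
  given member's subspace contains any of a handful of informative
  covariates shrinks as `p` grows, and accuracy approaches that of other
  forest methods only as the ensemble grows. `run_sensitivity_sweep()`
  exposes this trade-off over `r` and `M`.
* Ties in event times are handled by the standard risk-set conventions of
  the Nelson–Aalen and log-rank formulas; no Efron-style correction is
  applied.
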