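---
title: "Random-forest variable selection: methods, simulation designs and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest variable selection: methods, simulation designs and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

High-dimensional omics matrices (methylation, expression, proteomics,
metabolomics) typically have far more variables than individuals, sparse
relevant signal and strong correlation between variables. Random forests
handle this setting well and rank variables by *permutation importance*,
but a ranking alone does not say where relevance ends. `rfvarsel`
implements six procedures that turn the ranking into a selected set, and
the simulation and evaluation machinery needed to compare them.

Five of the selectors target **all relevant** variables — every variable
carrying information about the outcome, including correlated, redundant
ones, which is what you want when the goal is interpreting pathways and
networks rather than building the leanest possible predictor. The sixth,
recursive feature elimination (RFE), deliberately pursues the opposite
goal of a **minimal** predictive set and serves as the contrast.

# The importance measure

All methods build on the same engine (the `ranger` implementation of
random forests) with one importance definition: for each tree, predict
the tree's out-of-bag (OOB) observations before and after permuting one
variable's values, and average the performance drop over trees (accuracy
for classification, MSE for regression; signed so that relevant
variables score positive). Two deliberate choices:

* **Raw, not scaled.** The importance is *not* divided by its standard
  error. The scaled Z-score version is known not to be normally
  distributed, which would invalidate the parametric (Altmann) selector
  fitted on top of the null importances.
* **Impurity importance is not offered.** The mean decrease of the Gini
  index is biased (e.g. towards variables with many split points) and is
  excluded by design.

A variable that is never used in any tree has importance exactly zero;
trees without OOB observations contribute nothing. Each per-tree
permutation uses its own random stream, and a single top-level seed
derives all per-forest and per-permutation seeds, so every result in the
package is bit-reproducible.

The default forest parameterization is `num_trees = 10000`,
`mtry = 33%` of the number of variables and a minimal terminal-node size
of `10%` of the sample size. Those are benchmark-calibrated values for
n ≈ 100, p ≈ 5000 data; users with other shapes should revisit them.
Boruta is the exception: it runs with the conventional defaults of its
reference implementation (`mtry = sqrt(p)`, node size 1 for
classification, 5 for regression), because its shadow-variable contest
was calibrated under those.

## Hold-out importance

OOB null importances are *positively skewed*: selection effects during
tree construction let some null variables look mildly helpful on the
same data they were chosen on. The Vita selector therefore uses a
cross-validated variant: the data are split into two equal halves
(stratified by class for classification), one forest is trained per
half, each forest's importance is computed on the *other* half, and the
two scores are averaged. On independent data the selection effect
vanishes and the null distribution becomes symmetric around zero —
which is exactly what Vita exploits. `holdout_importance()` performs one
such split per call (two forests); the split and both forests derive
from the call's seed.

The half-split halves the effective sample size; node sizes resolve
against the training half. For very small n the hold-out scores become
noisy, and below n = 4 the split is refused.

# The six selectors

**Boruta** (`select_boruta`). Each run appends one freshly permuted
"shadow" copy of every undecided variable, fits a forest on real +
shadow variables, and counts a *hit* for an undecided variable whose
importance beats the best shadow. Cumulative hits are tested after every
run against Binomial(runs, ½) — two-sided, Bonferroni-corrected across
the variables still undecided — confirming clear winners and rejecting
clear losers; rejected variables leave the model. The run cap defaults
to 100; whatever is undecided then is reported `tentative` and *not*
counted as selected. Note an arithmetic floor: with p undecided
variables, no decision is possible before about log2(2p / pValue) runs,
so Boruta always trains at least ~20 forests on high-dimensional data.

**Vita** (`select_vita`). Computes hold-out importance once, then builds
an empirical null sample from the non-positive scores: negatives, zeros
and the negatives mirrored around zero. The p-value of a variable is the
fraction of the null sample at or above its importance; at the default
threshold `p_t = 0` a variable must strictly exceed every null value.
Because the null is estimated from the provided variables themselves,
the method requires a high-dimensional setting in which many variables
are uninformative; it errors out otherwise. Cost: exactly two forests,
by far the cheapest of the five all-relevant methods.

**r2VIM** (`select_r2vim`). Trains `no_runs = 20` forests differing only
in seed. In each run, importances are divided by the absolute value of
the run's most negative importance — the scale of what noise attains —
and a variable is selected if its *minimum* relative importance over all
runs is at least `factor = 3`. If a run has no negative importance
(minimum exactly zero, from unused variables), the most negative value
over all runs is substituted; if no run produced one, the null cannot be
scaled and the method errors.

**Perm** (`select_perm`). A classical permutation test on the outcome:
`no_perm = 500` outcome shuffles, each with a fresh forest, give each
variable its own null importance sample; the empirical p-value is the
fraction of null values at or above the original importance. We use
r/N rather than (r+1)/(N+1) so that p = 0 is attainable — required by
the default `p_t = 0`, which selects variables beating *all* their
permutation values. Expect roughly p/(no_perm + 1) false positives under
a complete null; the 500-permutation default is part of the method's
calibration, not an accuracy nicety.

**Altmann** (`select_altmann`). Same permutation machinery, but only
`no_perm = 50` shuffles: a normal distribution is fitted per variable to
the null importances by maximum likelihood (mean and N-denominator sd),
and the p-value is the upper tail of the original importance under the
fit. At `p_t = 0` a variable is selected when that tail probability
underflows to zero in double precision (z ≳ 39) — harsh, but reachable
by genuinely predictive variables, and the reason this selector is the
most conservative in the package. The per-variable null is used
(each variable compared with its own permutation distribution), matching
the parametric method this approach generalizes. When Perm and Altmann
run together, `run_benchmark()` trains the permutation forests once and
shares them; `perm_null_importance()` exposes the same reuse to users.

**RFE** (`select_rfe`). Iteratively drops the least important
`prop_rm = 10%` of variables (at least one), refitting and *re-ranking*
at every step — important with correlated predictors — until one
variable remains, recording each step's OOB error. The selected set is
the smallest one whose error is within `tol = 10%` of the minimum,
consistent with the method's minimal-set goal. Ranking ties (e.g. many
exact zeros) are broken by original column order, keeping the path
deterministic.

## Degenerate inputs and edge rules

* Constant variables get importance exactly 0 and can never be selected
  by any method (for Altmann this is the zero-variance null rule:
  p = 0 only if the original importance exceeds the null mean, else 1).
* Constant outcomes, single-class outcomes, and classification outcomes
  with more than two levels are rejected at dataset construction.
* Empty selections are legal results; downstream error evaluation then
  falls back to the outcome-mean / majority-class baseline and flags it.

# Simulation designs

## Design 1: nonlinear regression with correlated groups

Per replicate, six base variables x1..x6 ~ U(0, 1) are drawn per
individual. The outcome uses the first three:

y = 0.25 exp(4 x1) + 4 / (1 + exp(−20 (x2 − 0.5))) + 3 x3 + ε,
ε ~ N(0, 0.2)

The predictors never include the base variables themselves. Instead,
each base variable spawns a group of `group_size` correlated variables

v_ij = x_i + c_j N(0, 0.3),  c_j = 0.01 + 0.5 (j − 1)/(n − 1),

so within a group the correlation with the base variable (and, for
groups 1–3, with the outcome) decays from ≈ 0.99995 (c = 0.01) to
≈ 0.884 (c = 0.51). The remaining variables, up to 5000 in total, are
i.i.d. U(0, 1) noise. The causal truth is groups 1–3. The noise
multiplier multiplies the N(0, 0.3) draw — the only reading under which
the within-group correlation decays with j, which the design requires.

The null variant keeps all predictors but draws the outcome as the sum
of three independent N(0, 0.2) variables, independent of everything.
(The combining function is not prescribed by the design; any outcome
independent of the predictors preserves the null, and the additive
choice is the simplest.) Group sizes of 10 and 50 give 30 and 150
causal variables; defaults are 100 individuals, 5000 predictors.

## Design 2: multivariate-normal classification

Individuals are drawn from a zero-mean MVN with a user-supplied
covariance — in the original setting a covariance estimated from breast
cancer expression data. Estimating one from controlled-access data is
out of scope here, so `standin_covariance()` provides a synthetic
substitute: block-diagonal, unit variances, constant within-block
correlation, PSD by construction. It reproduces the qualitative
property that every variable is correlated with others, not the long-
range structure of real expression data; conclusions that depend on
realistic correlation tails need a real covariance matrix via
`read_covariance()`.

Per pair of replicates, 200 causal variables are chosen uniformly at
random — 25 for each effect size in {−3, −2, −1, −0.5, 0.5, 1, 2, 3} —
and the class-1 individuals (half of 200, assigned by a seeded shuffle)
have their means shifted by the effect size on those columns. Both
replicates of a pair share causal variables and effect sizes, so each
can select and train while the other estimates the classification
error, and the within-pair Jaccard index measures stability.

# Evaluation

Per replicate and method: FDR (|selected \ truth| / |selected|, defined
as 0 for an empty selection — no discoveries, no false ones),
sensitivity (|selected ∩ truth| / |truth|; undefined under a null model,
where the falsely-selected *count* is reported instead), and downstream
error (forest on the selected variables, RMSE or misclassification on an
independent replicate). Across replicates: per-variable empirical power
(selection frequency) and stability as the mean pairwise Jaccard index
|A∩B| / |A∪B| — within pairs for the paired design, over all replicate
pairs otherwise. The modified Jaccard |A∩B| / min(|A|, |B|) is also
reported; it is the honest choice when two selections differ
systematically in size. Two empty sets count as identical (index 1);
this cannot occur in the benchmark settings but needs a convention.
Summaries are medians and interquartile ranges; no significance tests
across methods are attempted.

# Problem sizes used by the shipped tests and acceptance script

The benchmark conditions (100 replicates, 5000 predictors, 10 000 trees,
500 permutations for Perm) are cluster-scale. The package's acceptance
runs use a desk scale chosen from runtime profiling on a single CPU:
10 replicates per scenario, 1000 predictors, 100 individuals, 50
outcome permutations for Perm and Altmann, with every other method
parameter at its default. Tree counts are allocated per batch to spend
the budget where forests are cheap: 1000 for Boruta (sqrt-mtry forests)
and Vita (two half-size forests) and 500 for RFE (~60 forests per
replicate) in the three-method and null scenarios, and 250 in the
six-method scenario, whose cost is dominated by the 51 shared
permutation forests. Consequences worth knowing:

* With 50 instead of 500 permutations, Perm's false-positive budget
  under a complete null grows from ~p/501 to ~p/51; the null-model
  check therefore asserts Perm's *rank* (most liberal method), not its
  count.
* The smaller noise pool (a tenth of the benchmark's) shrinks the
  absolute number of false positives available to r2VIM, so its median
  FDR sits below the benchmark value at this scale.
* Altmann's double-precision-underflow selection rule needs precisely
  estimated importances; at a few hundred trees its selected sets are
  small, which lowers its cross-replicate stability well below what it
  attains at 10 000 trees.

The distribution-shape property (OOB null importances positively
skewed, hold-out importances symmetric) is checked on one 5000-variable
null replicate with 1000 trees. Because per-variable importances at
finite tree counts are heavy-tailed, the sample third moment of a single
realization is outlier-dominated (it can land anywhere in ±20 even with
10 000 trees); the symmetry assertion therefore uses a quantile-based
skewness (α = 0.05) together with the positive/negative sign balance,
both robust to the tails, while the OOB assertion uses the moment
skewness, whose positive sign is stable.

# Known limitations

* Binary classification and regression only; no survival outcomes, no
  multiclass, no missing-value handling.
* The Sim-2 stand-in covariance is exchangeable-by-blocks; power
  estimates under it transfer only qualitatively to real expression
  covariance structure.
* Selector defaults were calibrated for n ≈ 100, p ≈ 5000; in
  low-dimensional data only Boruta retains its justification (the
  others estimate their null from the provided variables and need many
  uninformative ones).
* Perm is computationally expensive by construction (one forest per
  permutation); use Vita when its high-dimensionality assumption holds.
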