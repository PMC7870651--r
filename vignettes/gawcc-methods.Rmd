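---
title: "Two-stage wrapper feature selection with gawcc: model, operators, and design choices"
author: "gawcc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage wrapper feature selection with gawcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gawcc)
```

## The problem and the method

Omics-scale tabular data — gene expression, mass spectrometry, molecular
fingerprints — routinely carry thousands of measured features of which only
a handful discriminate the sample classes of interest.  Features fall into
three informal roles: *positive* features that help a classifier, *neutral*
features that merely add dimensionality, and *negative* features that carry
coherent but misleading structure and actively degrade generalization.
Wrapper feature selection searches the subset lattice directly, scoring
each candidate subset by the cross-validated performance of a learner, here
a support-vector machine.

`gawcc` implements a two-stage wrapper.  A candidate solution (CS) is a
variable-length, duplicate-free, sorted vector of 1-based feature indices.

**Stage 1 — genetic algorithm.**  A population of CSs (default 100) is
evolved with three operators:

* *mutation*: one randomly chosen position is overwritten by a uniform draw
  from $[1, n]$;
* *range crossover*: a contiguous window of one shared random length is
  drawn in each of two parents and the window contents are swapped;
* *elitism*: parents, children and mutants compete in one pool and the
  best `pop_size` by fitness survive.

After every operator the candidate is re-canonicalized — duplicates
removed, indices sorted — so candidates can shrink but never grow.  The GA
stops when the best fitness has not changed for `stagnation_window`
(default 10) consecutive generations.

**Stage 2 — world competitive contests (WCC).**  The GA's whole terminal
population seeds the WCC optimizer.  Per iteration every member gets
`match_time` change attempts; one attempt applies three operators in
sequence, each followed by a greedy accept-only-if-strictly-better step:

* *attacking* (large perturbation): $k \sim U[1, |CS|]$ positions are
  overwritten with uniform draws from $[1, n]$;
* *transferring* (recombination with the elite): for $R \sim U[1,
  |\text{top}|]$ rounds, a donor among the `top_count` (default 5) current
  best members is chosen and $k$ of the candidate's positions are
  overwritten with randomly chosen donor values;
* *passing* (small perturbation): a single position is overwritten.

Fitness is the mean held-out accuracy under stratified $k$-fold
cross-validation (default fivefold) for classification, and the negated
pooled RMSE for regression, so both tasks are maximized uniformly and the
greedy acceptance rule reads the same way.  Because elitism retains the
incumbent and the WCC accepts only strict improvements, the best-fitness
trajectory of every run is non-decreasing — this is asserted throughout
the test suite.

## Scoring details

The default learner is an RBF-kernel SVM (libsvm via **e1071**) with $C =
1$ and $\gamma = 1/d$ where $d$ is the number of selected features;
multi-class problems use libsvm's native one-vs-one voting.  No learner
hyperparameter is tuned.  The learner is a pluggable contract — any list
providing `fit`, `predict` and `decision` functions can be injected, and
the test suite exercises a nearest-centroid learner through the same path.

Within `evaluate_subset()` imputation (training-fold means) and
standardization are fitted on the training folds only and applied to the
held-out fold, so no information leaks across the CV boundary.  The global
`canonicalize()` (mean/median/drop-row imputation, min-max or z-score
scaling) exists for filter methods and parity experiments; zero-variance
columns map to all-zero under both scalings rather than dividing by zero.

The metric panel reports SEN, SPC, PRE, FPR, ACC, F-measure, Cohen's kappa
and rank-based AUC (the normalized Mann–Whitney statistic, ties counting
one half; macro one-vs-rest for more than two classes).  Kappa is the
standard $(p_o - p_e)/(1 - p_e)$ on the pooled contingency table.
Zero-denominator cells are reported as 0 with a degeneracy flag rather
than `NaN`.

## Initial candidate length bounds the reachable subset size

Every operator can only keep or reduce a candidate's length (duplicates
introduced by an overwrite are removed), so the largest initial length is
an upper bound on the size of any subset the search can ever return.  The
default initial candidate is therefore built from $n$ index draws *with
replacement*, which after deduplication leaves roughly $0.63\,n$ unique
features and frequent repeats — consistent with the method's emphasis on
initial candidates that start at one nominal length but immediately vary.
A $\sqrt n$-style initial length, attractive for keeping early models
small, was rejected: on a 10-feature benchmark the exhaustive
cross-validated optimum typically uses 5–8 features, which a
$\sqrt{10} = 3$-draw initialization can provably never reach.  Users who
want small models on very wide tables can set `init_length` explicitly.

## Rate semantics and other open choices

Published descriptions leave several details open; the package fixes them
as follows and exposes each in configuration:

* *30% mutation and crossover rates*: per generation,
  `crossover_rate * pop_size / 2` random pairs each produce two children
  and `mutation_rate * pop_size` random members produce one mutant each;
  offspring join the parents in one elitism pool.  Parents' scores are
  cached, not re-evaluated.
* *Operator order within a WCC attempt*: attacking, then transferring,
  then passing — large to small perturbation, each greedily gated.
* *Greedy ties*: a proposal that merely matches the incumbent's fitness is
  rejected (strict reading of "accepted if the accuracy increases").
  This prevents neutral drift but also means accuracy plateaus freeze the
  candidate's composition; see Limitations.
* *Elitism tie-breaks*: equal fitness prefers the shorter candidate, then
  lexicographically smaller indices, making selection fully deterministic.
* *$k$ in attacking*: drawn per application and bounded by the candidate's
  current length (a bound of $n$ would ask for more overwrites than there
  are positions).
* *EN filter*: implemented as information gain (label entropy minus
  conditional label entropy given the equal-frequency-binned feature),
  since the entropy filter is used for supervised reduction in the
  filter-then-wrapper variant.  Under identical binning this coincides
  with the mutual-information filter up to the logarithm base (EN in nats,
  MI in bits); the two are kept as separate, separately-tested entry
  points with that equivalence asserted as a property.
* *Fisher score*: $\sum_c n_c(\mu_c - \mu)^2 / \sum_c n_c s_c^2$ with
  population within-class variances.  A feature with real between-class
  separation and zero within-class variance scores $+\infty$ (a perfect
  discriminator), while a globally constant feature scores the degenerate
  null 0.
* *Laplacian score*: 5-nearest-neighbour graph, heat kernel with width set
  to the median pairwise squared distance, symmetrized by taking the
  maximum of the two directed weights; lower scores are better.
* *Execution comparisons*: Welch's *t*-test by default (for two groups it
  is the unequal-variance analogue of one-way ANOVA), with a Wilcoxon
  rank-sum alternative; two constant equal groups give $p = 1$ by
  convention.
* *Identical budgets*: methods are compared under identical
  evaluation-count budgets (population sizes and iteration counts) rather
  than wall-clock time, for reproducibility.

All randomness — fold assignment, initialization, operator draws — flows
from a single integer seed, so a fit is a pure function of its inputs and
re-running with the same configuration reproduces the report bit for bit.
When several runs must be compared on the same objective, a single
`cv_plan` can be passed to every run so that the fitness landscape is
fixed and only the search randomness varies.

## The synthetic benchmark generator

`synth_classification()` plants the three feature roles explicitly:
positive features are class-conditional Gaussians whose class means are
separated by `effect_size * noise_sd`; neutral features are
label-independent Gaussians; negative features carry class structure at
the same effect size for one shared random relabeling of the samples, so
they present coherent but wrong signal rather than mere noise.  A
`redundancy` knob turns some positive features into noisy copies of
others.  `synth_regression()` sums the positive features into a
linear-plus-noise target and gives negative features correlation with a
permuted copy of that target.  Classes are balanced to within one sample
by default, matching the near-balanced benchmark tables the method was
designed around.

What the generator does *not* emulate: real marginal distributions
(heavy tails, zero inflation), batch structure, feature-feature
correlation beyond the redundancy knob, and label noise.  Passing tests on
these benchmarks therefore demonstrates that the optimizer, scorer and
protocol behave as specified — not that any particular accuracy will be
attained on a given real dataset.

## Problem sizes used by the test suite

The acceptance-style tests run at desk scale on one CPU: the
exhaustive-oracle check uses a 10-feature, 60-sample table (all 1023
subsets scored once, 20 independent two-stage runs at the published
defaults); the planted-recovery check uses 50 features and 200 samples
with a reduced search budget (population 30, 8 WCC iterations); the
method-ordering experiment uses 25 features and 100 samples with 20
executions per method.  These sizes are the package's own choices to keep
the whole suite in the minutes range; the search budget scales up by
configuration only.

## Known limitations

* The strict-improvement acceptance rule cannot cross or prune along
  fitness plateaus.  On very easy problems where cross-validated accuracy
  saturates at 1.0 — including strongly separated synthetic benchmarks —
  subset composition freezes early: no proposal can strictly improve on a
  perfect score, so neutral features that entered early are never removed
  and the precision of the recovered set degrades even while accuracy is
  perfect.  On such saturated problems no selector can strictly beat an
  already-perfect all-features baseline either.  This is a faithful
  property of the specified acceptance rule, not an implementation
  artifact.
* Accuracy is the classification fitness; heavily imbalanced tasks would
  need a different fitness (the learner contract and `eval_result` panel
  already compute the alternatives, but the optimizers currently maximize
  accuracy / negated RMSE only).
* The printed kappa column of the method's published tables behaves
  inversely to standard Cohen's kappa; this package reports the standard
  definition and makes no attempt to reproduce that column.
* Filter scores are univariate (except the Laplacian score) and are
  computed on the full table, not per fold.

## A worked example

```{r example, eval = FALSE}
bench <- synth_classification(n_samples = 100, n_positive = 4,
                              n_neutral = 17, n_negative = 4,
                              effect_size = 1.2, seed = 2026)
plan <- cv_plan(bench$table, 5, seed = 2026)
run_baseline_svm(bench$table, plan)$fitness   # all 25 features

fit <- feature_select(bench$table, method = "ga_wcc", plan = plan,
                      seed = 1, ga = ga_config(pop_size = 20),
                      wcc = wcc_config(match_time = 1, iterations = 6))
summary(fit)
recovery_metrics(coef(fit), bench$truth)
plot(fit)   # non-decreasing best-fitness trajectory
```
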