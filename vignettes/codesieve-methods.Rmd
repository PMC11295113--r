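---
title: "CodeSieve: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CodeSieve: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
component assumes, which parameters matter, what the synthetic generator
does and does not emulate, and where a genuinely open design choice was
settled. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

CodeSieve operates on *ancestor-closed one-hot matrices*. Long-format
records `(patient, date, code)` are aggregated per patient into fixed-day
windows — 90 days standing in for "three months" of diagnosis records, 180
days for "six months" of drug dispensations. Calendar-month arithmetic is
deliberately avoided: month lengths vary, fixed day counts are exactly
reproducible. Windows are anchored at each patient's first event; empty
windows produce no record.

Every aggregated record is one-hot encoded over the union of observed codes
and *all of their ancestors* in the code tree, so a record carrying `I251`
also carries `I25`, `I20-I25` and its chapter. This closure is an invariant
of the `RecordMatrix` container (features are rows of an underlying
`SummarizedExperiment`; records are columns) and is checked by
`validateClosure()`. Two consequences shape everything downstream: parent
columns are deterministic ORs of their children, and column redundancy is
the norm rather than the exception — precisely the regime in which
unsupervised selection is hard and depth information is useful.

Hierarchies come in two flavours. ATC codes are fixed-width (1/3/4/5/7
characters), so ancestors are prefix truncations and need no table. ICD
block codes such as `I20-I25` cannot be derived from child strings, so the
ICD tree is table-driven (`code,parent,label` CSV). Codes absent from the
table are attached as depth-0 singleton roots with a warning rather than
rejected: national ICD extensions make complete tables unrealistic, and
dropping unknown codes would silently change the feature space. Roots sit
at depth 0 throughout; nothing in the loss-weighting formula below is
meaningful without fixing this origin, and depth 0 gives the most general
codes the maximal weight 1.

## The selector suite

All selectors consume a records-by-features binary matrix and emit a
`SelectionResult` whose `selected` indices are unique, in range and at most
`nBest` long. Scores are oriented "larger = more selected" in every method
so downstream code never needs per-method conventions.

**Laplacian score.** A binary symmetric (union) 5-nearest-neighbour graph
is built over the *records*. Binary edge weights are the heat-kernel
similarity in the large-bandwidth limit. With degree matrix `D` and
Laplacian `L = D − W`, the score of feature `f` is
`(f̃ᵀ L f̃)/(f̃ᵀ D f̃)` after removing the degree-weighted mean; the
`nBest` smallest scores win, and stored scores are negated to keep the
package-wide orientation. A constant column has a 0/0 score; it is assigned
the worst possible value (never selected) with a warning — on sparse code
data constant columns are common and must not crash a run. The graph is
built over records, not features: that is what the original Laplacian-score
and MCFS formulations prescribe, and it is the only reading under which
their score formulas type-check. A feature-graph variant is deliberately
not offered.

**MCFS.** The same graph yields the generalized eigenproblem
`L y = λ D y`, solved through the symmetric normalized Laplacian; the
trivial constant-like eigenvector is dropped and the next `nEigvecs`
(default 5, configurable — the count is not dictated by the method and must
be exposed) are each regressed on the features under an L1 penalty. The
path is computed by an exact lasso homotopy (LARS with the lasso
modification) on centered data, stopped at the breakpoint where the active
set reaches the cardinality budget (default `nBest`). The homotopy matters
for two reasons: the budget semantics ("the solution with at most k active
features") is exact rather than grid-approximated, and exact duplicate
columns cannot split a coefficient — the first duplicate to enter stays
active, later ones remain tied to the boundary and are excluded when their
Gram matrix becomes singular (reciprocal condition number below 1e-10).
A feature's score is its largest absolute coefficient across eigenvectors.

**AEFS.** A single-hidden-layer autoencoder minimizing squared
reconstruction error plus `α Σⱼ ‖W⁽¹⁾ⱼ.‖₂` (the row-wise group penalty; the
notation "L1,2" in parts of the literature denotes exactly this
sum-of-row-norms term) plus Frobenius weight decay `β/2 Σ‖W‖²`. Defaults
α = 0.001 and β = 0.1; hidden width defaults to `⌈p/2⌉` capped at 256,
trained 200 epochs with Adam at 0.001 — the width, budget and optimizer are
not fixed by the method, so all are exposed. Scores are first-layer
weight-row norms. Note that with both penalties off, a structurally absent
(all-zero) column receives no gradient at all and keeps its random
initialization norm; it is the weight decay that drives dead rows to the
bottom of the ranking.

**PFA.** Features are represented by their rows of the PCA loading matrix
over `⌈p/2⌉` components. PCA is computed *exactly* but incrementally: the
column means and cross-product matrix are accumulated over row batches
(default `2p` rows), so memory stays bounded on tall matrices while the
eigendecomposition equals the one-shot result to machine precision — this
replaces an approximate streaming update with something that is both
bounded-memory and exactly testable. k-means (`nBest` clusters, seeded)
runs on the loading rows; each cluster returns the feature nearest its
centroid, ties to the lowest index. Empty-cluster fits are retried with
derived seeds at most five times, then error.

**Concrete autoencoder.** The encoder is a selector layer of `nBest`
neurons, each holding a logit vector over all `p` features. Per training
step one Gumbel matrix `G` is drawn and the layer outputs
`softmax((logits + G)/T) · x`. The temperature follows
`T(e) = 20 · (0.01/20)^(e/E)` — exploration at `T ≈ 20`, a near-argmax at
`T ≈ 0.01`. The decoder (two hidden layers of 64 leaky-ReLU units, sigmoid
outputs) is trained by binary cross-entropy over all original features;
Adam optimizes decoder and logits jointly. At inference the selector is a
hard argmax without noise; `selected = unique(assignment)`, so duplicated
neuron choices shrink the selection — a documented property of the method,
not a defect of the implementation.

The **weight adjustment** (CAEWW) multiplies feature `F`'s per-element
cross-entropy term by `w(F) = 1/(1 + depth(F))` and normalizes the weighted
sum by `Σ w` rather than by the feature count. The normalization is an open
choice the formula itself does not settle; dividing by `Σ w` keeps the loss
(and hence effective learning rate) on the same scale as the unweighted
variant, which is what makes the paired CAEWW-vs-CAENW comparisons
meaningful. With all weights equal to 1 the weighted code path is
bit-identical to the unweighted one — a regression test enforces this.

### Training budgets at desk scale

The reference regime for the concrete autoencoder is 1000 epochs at batch
size 64 over data sets with hundreds of thousands of records — millions of
optimizer steps, during which logits separate slowly at learning rate
0.001. The package's experiments run on a few hundred records, where 200
epochs at batch 64 would provide only ~750 steps: the logits cannot outgrow
the Gumbel noise before the temperature collapses, and selection degrades
to chance. The recovery and weighting experiments therefore use batch 16
and learning rate 0.015 at 200 epochs (several thousand steps, total logit
displacement comparable to the reference regime). These are the
pre-registered budgets baked into `caeRecoveryExperiment()` and
`depthWeightingExperiment()`; the method defaults remain the reference
values.

## Evaluation tracks

**Reconstruction.** A feed-forward network (two hidden layers of 64
leaky-ReLU units, 10% dropout, sigmoid outputs, BCE loss, Adam at 0.001,
100 epochs, batch 64 — architecture fixed, budget exposed) maps the
selected columns to all original columns. The baseline predicts, for every
feature, its training-set majority value regardless of input; exact 50/50
ties break to 0, absence being the majority regime of sparse code data. For
the baseline's *cross-entropy* the hard 0/1 mode is useless (a single miss
gives unbounded loss), so the baseline probability is the training
frequency clipped to `[1e-7, 1−1e-7]`; its *accuracy* uses the hard mode.
Accuracies are compared with a two-sided t test across features — paired by
default, because method and baseline are evaluated on the same features;
Welch's unpaired variant is available by flag. A zero-variance difference
vector makes the paired statistic degenerate: the report then carries
`p = 1` (all differences zero) or the machine-epsilon bound, with an
explicit flag rather than a silent `NaN`.

**Outcome case study.** The minority class is upsampled *inside* each
cross-validation training fold (and for the final fit), while validation
folds keep the natural imbalance. Balancing before the fold split would
copy minority rows into validation folds and systematically favour overfit
hyperparameters; with the leak-free order, CV rankings transfer to held-out
patients. The tuning grid is fixed and documented: tree depth {3, 5, 7},
learning rate {0.05, 0.1, 0.3}, {100, 300} trees, minimum child weight
{1, 5}; the selection criterion is mean validation AUC. Classification
metrics use the 0.5 probability threshold (a documented convention — the
alternative of a tuned threshold is out of scope). DeLong's test compares
correlated AUCs (delegated to pROC; the reported AUCs equal the
Mann-Whitney statistic); McNemar's test uses the exact binomial form when
the discordant count `b + c < 25` and the continuity-corrected chi-square
`(|b−c|−1)²/(b+c)` otherwise, with `p = 1` and a degeneracy flag at
`b + c = 0`. Tree Shapley attributions come from the gradient-boosting
model's exact tree-path algorithm; per-row attributions plus the bias term
reproduce the margin output (additivity is asserted in the tests). Depth
and importance comparisons across methods use two-sided Welch t tests — the
robust default when selections differ in size — with the weight-adjusted
CAE as the reference.

## The synthetic generator

`generateRecords()` draws, per patient, a set of active latent comorbidity
factors (Bernoulli, default probability 0.3). Each factor owns a fixed set
of leaf codes (the leaves are partitioned among factors) and emits each
owned code with probability 0.9 per record; records carry dates spanning
multiple aggregation windows; independent leaf noise fires at rate 0.01.
With `redundancyRate > 0`, a factor's sibling codes share one emission draw
per record, so siblings co-fire deterministically — the planted analogue of
perfectly redundant code pairs. Outcomes follow a logistic model over a
sparse set of planted codes (default five codes at log-odds weight 1.5);
the intercept is calibrated by bisection so the expected prevalence hits
the target (default 5%), and the run errors out if the achieved expectation
is off by more than 20% relative rather than silently shifting the regime.

What the generator emulates: sparse ancestor-closed binary matrices,
correlated code blocks, per-patient window structure, a rare outcome driven
by a handful of codes. What it does not: realistic marginal frequencies of
individual codes, coding-practice drift over calendar time, multi-morbidity
correlation *between* factors, or any linkage noise in outcome
ascertainment. Passing tests therefore demonstrate that the algorithms do
what their formulas claim under controlled redundancy — not that any
particular selection on real registry data would be clinically superior.

Experiment scales are fixed inside the experiment functions: generator
recovery uses 400 records × 64 columns (8 generators × 8 duplicates, 5%
flip noise); the weighting experiment uses 8 parent–children units with
child firing probability 0.55 — chosen because at that rate the *ideal*
unweighted reconstruction losses of picking a parent versus a child are
near-equal, so any systematic shift toward ancestors is attributable to the
depth weights; the end-to-end outcome experiment uses 1700 patients
(≈5000 aggregated records, 126 features, 16 factors). The bundled demo
benchmark runs all six selector variants on a 150-patient cohort in well
under a minute.

## Numerical conventions

* Tie-breaks are uniform: ranking ties, argmax over logits, and k-means
  nearest-centroid ties all resolve to the lowest index.
* All randomness flows through explicit seeds; `withSeed()` restores the
  caller's RNG state, and the benchmark derives per-stage seeds from a
  single master seed and the stage name (kept below 2³¹).
* Selector logits initialize from `N(0, 0.01²)` — symmetric, small
  variance, seeded; neural weights use Glorot-scaled normal draws.
* Probabilities inside cross-entropies are clipped to `[1e-7, 1−1e-7]`.
* The LARS homotopy treats correlations within `1e-10` of the boundary as
  ties and excludes features whose Gram matrix falls below `rcond 1e-10`.
* Degenerate inputs fail loudly and early: single-patient splits, absent
  outcome classes, constant score vectors in ROC comparisons, selections
  smaller than three features in comparison tables, non-finite training
  losses (reported with the epoch and learning rate).

## Known limitations

* Selector internals densify the record matrix; the implementation targets
  desk-scale experiments (hundreds to a few thousand records, hundreds of
  columns), not registry-scale corpora.
* The concrete selector offers no regularizer against duplicate neuron
  choices; selections smaller than `nBest` are expected behaviour.
* Reconstruction reports a feature-wise standard error convention of its
  own; it does not attempt to reproduce any particular interval convention
  used elsewhere.
* The ICD fixture table is a miniature, synthetic-by-construction excerpt
  shaped like the real hierarchy; it ships for examples and tests, not as a
  licensed code set.
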