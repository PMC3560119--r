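---
title: "Methods: multimodal relapse prediction and disease-evolution monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal relapse prediction and disease-evolution monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscctrack)
```

## Scope and data model

`oscctrack` models post-remission relapse of oral squamous cell
carcinoma from four baseline data sources — clinical and imaging feature
tables, and tissue / blood one-channel expression arrays — plus a
three-visit blood-expression time course (baseline, follow-up #1,
follow-up #2). The relapse label is binary and, in the temporal arm,
*absorbing*: a diagnosed relapse terminates remission, so once the
relapse state is 1 it stays 1 at later visits. All expression values are
treated as log2 intensities.

No cohort of this kind is publicly available, so the package treats the
synthetic-data generator as a first-class module: it emulates the study
conditions the pipeline is designed for (86 patients with 26 relapsers;
45,015 probes of which QC retains 33,491; a 23-patient, 11/12 follow-up
cohort) with known planted ground truth, and every downstream guarantee
is stated as a property of recovery of that truth.

## Preprocessing

* **Sparse features.** A feature is dropped when its missing fraction
  strictly exceeds 0.9; a column at exactly 90% missing is retained.
* **Imputation.** Nominal gaps take the column mode (ties broken toward
  the smallest value so the result is row-order invariant), numeric gaps
  the column mean. Imputation precedes SMOTE because interpolation needs
  complete numeric vectors.
* **SMOTE.** The minority class is oversampled to a target
  minority:majority ratio (default parity). Each synthetic row
  interpolates the numeric features between a minority seed and one of
  its `k = 5` nearest minority neighbors — Euclidean distance on
  standardized numeric features, nominal features copied from the seed
  and excluded from the metric. Synthetic rows are flagged, and inside
  `evaluate()` SMOTE is re-fit within each training fold only: a
  held-out patient never contributes to the synthetic rows of its own
  fold.
* **Probe QC.** Control probes, all but the first member of each
  duplicate group, low-quality-flagged probes and probes with > 50%
  missing values are removed. The 0.9 cutoff is stated for clinical
  features only; 0.5 for probes is this package's configuration choice,
  exposed as an argument. Duplicate resolution keeps the first
  occurrence rather than averaging — the simplest deterministic rule.

## Gene ranking

The two-class statistic is the moderated difference
`d = (m1 − m0) / (s + s0)`, with `s` the pooled two-sample standard
error and `s0` the median (configurable quantile) of all per-gene
standard errors. The full minimization grid for `s0` used by some SAM
implementations is deliberately simplified to a quantile; the choice is
a config value, not a claim about any particular reference
implementation. Significance is assessed by label permutation — all
distinct relabelings when there are few enough, otherwise seeded
sampling with an add-one correction — pooling the order statistics of
`|d|` across genes and permutations, followed by Benjamini–Hochberg
step-up. Pooling makes q-values monotone in `|d|`, which gene-specific
nulls would not guarantee. Fold change is the *linear-scale* ratio of
class means and is tested two-sided (`max(FC, 1/FC)`), inclusive at the
threshold.

For the time course, each patient × gene trajectory is first reduced to
a scalar — the signed trapezoidal area across visits (a least-squares
slope is offered as an alternative) — and genes are ranked by the
Wilcoxon rank-sum (midranks) of these summaries between relapsers and
non-relapsers, with the same permutation machinery over group labels.
The reported fold change maps the per-visit group difference back to the
linear scale. A per-patient scalar summary is required before a rank
test across patients; the area was chosen because it uses every slice
without assuming linear trends.

## Feature selection

CFS scores a subset by `merit = k·r_cf / sqrt(k + k(k−1)·r_ff)` where
both correlation terms are symmetrical uncertainties on discretized
features (equal-frequency, 4 bins). Search is forward best-first with a
stall limit of 5 non-improving expansions, ties resolved toward smaller
subsets and then lexicographic feature order, making the selection
invariant to column order. The wrapper selector uses the same search
skeleton but scores a subset by stratified 5-fold inner-CV accuracy of
the target learner, with the fold assignment fixed once per run; the
empty subset (majority vote) is the baseline candidate, so the returned
subset can never score below it.

## Classification, evaluation, fusion

Naive Bayes (Laplace-smoothed nominal likelihoods, Gaussian numeric
likelihoods) and an information-gain decision tree serve as the
reference learners, provided through `e1071` and `rpart`; any further
learner (SVM, random forest, neural network, Bayesian network)
participates through the plugin contract — a factory
`function(table, seed)` returning a scoring function. The pipeline and
the fusion rule, not the base learners, are the substance here.

`evaluate()` offers stratified 10-fold CV (per-fold metric panels
averaged, dispersion reported as the standard deviation across folds)
and leave-one-patient-out (metrics pooled over the n held-out
predictions). The panel is accuracy, sensitivity (relapse class),
specificity, Cohen's kappa `(p_o − p_e)/(1 − p_e)` and AUC in the
rank/Mann–Whitney formulation with midrank ties.

Per-source predictions merge by weighted majority voting. The original
study does not state the weights that achieved complete discrimination,
so weight fitting here is an explicit reconstruction: weights default to
normalized per-source accuracy, with uniform weighting for ablation. An
exact tie calls relapse — in surveillance the false negative is the
costly error.

## Personalized genetic signature

Per patient, genes with `|log2 difference| ≥ 1` between the cancerous
(pre-treatment) and cancer-free (first-remission) profiles form the
signature, with a top-50 fallback so the set is never empty unless the
profiles are identical; weights are proportional to `|d_g|` and sum
to 1. Each later visit is compared with both references by Pearson
correlation (qualitative) and the weighted Euclidean distance
(quantitative), restricted to signature genes. The monitoring flag
raises when a visit sits strictly closer to the cancerous profile; an
exact distance tie resolves to cancer-free to avoid spurious alarms. The
two measures are reported side by side and never aggregated into a
single prognosis call, because no aggregation rule is defined by the
design being modeled. Signatures are computed per patient and never
pooled; signature genes are not fed into the DBN.

## The dynamic Bayesian network

The temporal model is a stationary 2-TBN over discretized gene states
plus the binary absorbing relapse node: one initial network (slice 1,
intra-slice parents only) and one transition network (intra-slice
parents at t plus inter-slice parents at t−1) shared across both visit
transitions — three visits are too short to fit non-stationary
transitions.

**Discretization.** Equal-frequency, 3 bins per gene
(under / normal / over-expression), boundaries learned on training
patients pooled across slices and applied unchanged to held-out
patients. Boundaries are placed at midpoints between consecutive
distinct observed values, each target quantile snapping to the widest
value gap within half a bin of cumulative mass. For continuous data this
is essentially the empirical quantile; for clustered data it places the
boundary in the density valley instead of on a tied value (which would
empty a bin) or inside a cluster (which sampling fluctuations of the
state marginals would otherwise cause). A constant gene falls back to a
single bin with a warning.

**Scoring and search.** Families are scored by BDe (Dirichlet
pseudo-counts `ess/(q·r)`, default `ess = 1`) or BIC; the score is
decomposable, so a single-edge move re-scores only the affected
families. `max_parents = 3` bounds CPT size at cohort scale. Greedy
search hill-climbs over add/delete/reverse (intra) and add/delete
(inter) moves with random restarts; simulated annealing accepts random
proposals with probability `min(1, exp(Δ/T))` under geometric cooling,
returns the best structure seen, and finishes with a greedy quench so
the result is at least a local optimum. Both searches and the schedule
are fully seeded. The scoring function and search granularity of the
original system are unreported, so both scores and all schedule
parameters are exposed as configuration.

**Inference.** Posteriors on the unrolled network are computed exactly
by variable elimination with a greedy min-size elimination order. The
contract is exactness (the test suite checks equality with full-joint
enumeration to 1e-9 on networks of up to 12 binary nodes); at these
problem sizes a junction tree brings no additional capability.
Inconsistent evidence (zero-probability, or two states asserted for one
node) raises an explicit error.

**Forecasting and evaluation.** `predict_relapse()` returns
`P(relapse_s = 1 | evidence)` for every slice after the last evidence
slice, thresholded at 0.5 (configurable for sensitivity-first
operation). `lopo_evaluate()` re-fits discretization boundaries, the
structure and the CPTs inside every training fold, then scores the
held-out patient at two evidence horizons: baseline only (forecast at
follow-up #1) and baseline + follow-up #1 (forecast at follow-up #2).
Because pooled and class-averaged rates differ on unbalanced cohorts —
and the pooling convention behind published per-horizon summaries is
ambiguous — both the pooled accuracy and the macro (class-balanced)
accuracy are reported.

## Synthetic study conditions

`cohort_spec()` defaults encode the baseline-arm conditions: 86 patients
(26 relapsers / 60 non-relapsers), ~62 clinical and ~16 imaging
features, 45,015 probes with flag fractions chosen so QC removes
2251 control + 4501 duplicate + 3601 low-quality + 1171 high-missing
= 11,524 probes, retaining 33,491. Expression is emitted on a log2-like
scale — non-DE genes ~ Normal(8, noise_sd), DE genes shifted by
`log2(fold_change)` in relapsers — so "fold change" is well defined for
the ranking filter. Nominal clinical features draw from 2–4 category
distributions with class-dependent probabilities for the informative
subset; missingness is injected completely at random (the mode/mean
imputation assumes no informative missingness), with designated
heavy-missing columns above 95%.

The default generating DBN has 9 ternary gene nodes and the relapse
node, matching the scale of the final monitoring model: each gene
persists in its state across visits with probability 0.98 (a doubly
stochastic transition row, so state marginals stay uniform and
equal-frequency discretization can recover the states), and the relapse
hazard depends on the first gene's state, `(0.01, 0.03, 0.98)` for
under/normal/over-expression, with 10% prevalent relapse at baseline.
Emissions are state-conditional Gaussians with means 2 log2-units apart
and sd 0.25 — noise at a quarter of the state spacing, typical of array
replicate variability and small enough that the discrete dynamics are
actually observable. These strong-signal settings are deliberate: with
200 patients × 3 visits, a transition row receives on the order of 130
observations, so only strongly expressed CPT rows are estimable to
within a few percent; a weak-signal truth would make parameter recovery
a test of sampling noise rather than of the estimator. Visits are
modeled as ordinal slices only — the design being emulated states no
calendar spacing beyond a 24-month span.

When a fixed class split is requested (e.g. 11 relapsers of 23),
trajectories are drawn by per-patient rejection sampling conditioned on
the final-visit relapse state, which preserves the within-class
trajectory distributions. The relapse node is absorbing during sampling
regardless of its CPT.

**What the generator does not emulate:** probe-level chemistry and
spatial artifacts, array batch effects and normalization differences
(the emulated design holds platform and extraction software fixed),
informative missingness, survival times beyond the three-visit relapse
indicator, and correlated gene modules. Passing tests therefore show
that the algorithms recover the structure they were designed to recover
under clean, identifiable conditions — they do not certify performance
on real cohorts with batch structure or weak effects.

## Numerical choices and degenerate inputs

* Permutation p-values use an add-one correction when sampled and exact
  counts when enumerated; BH step-up is applied afterwards.
* `s0` at the median of per-gene standard errors; `d` is antisymmetric
  under label swap by construction.
* CFS/wrapper ties: higher score, then smaller subset, then
  lexicographic order.
* Kappa on a degenerate table (`p_e = 1`) is defined as 1 when agreement
  is perfect and 0 otherwise; AUC over constant scores is 0.5 by
  midranks; both follow from the limiting formulas.
* CPT smoothing `(counts + pseudocount)/(total + pseudocount·r)` with a
  uniform fallback for unseen parent configurations at pseudocount 0.
* Distance ties in the signature go to cancer-free; fused-vote ties go
  to relapse; both are documented policies, opposite by design (alarm
  suppression vs. alarm preference) because the cost structures differ.
* Constant visit vectors: correlation is reported `NA`, distance still
  computed.

## Problem sizes in the test suite

The suite runs the inference oracle on 200 random networks (≤ 12 binary
nodes against full-joint enumeration), the structure-space oracle on 100
seeded 4-variable problems (greedy with 16 restarts; annealing from T₀=3,
cooling 0.95, 120 moves per temperature, quenched), ground-truth recovery
at 200 patients × 3 slices, LOPO monitoring on an 18-patient noiseless
cohort plus 20 label-shuffled replicates of 14 patients, and SAM
calibration at 500 genes × 20 seeds. These sizes were chosen so each
property is decided with clear statistical margin while the whole suite
stays fast enough to run routinely.

## Known limitations

* The wrapper selector and fusion weights reconstruct unspecified
  details of the emulated design; they are configuration, not claims.
* Exact inference scales exponentially in clique size; the intended
  regime is ≤ ~12 nodes per slice with ≤ 3 parents, ample for
  nine-gene monitoring models but not for genome-scale networks.
* LOPO with per-fold structure search is O(n · search); at hundreds of
  patients a fixed-structure mode (supply the learned structure and
  re-fit only CPTs per fold) is the practical alternative.
* The NB/DT learners are reference implementations of the plugin
  contract; no hyperparameter optimization is attempted.
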