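---
title: "hepascreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepascreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepascreen)
```

`hepascreen` builds stacked QSAR classifiers for drug-induced liver injury
(DILI) and screens hepatotoxic ingredients in multi-ingredient herbal
medicines through three complementary evidence channels. This vignette is
the package's own account of the methods: the model and its assumptions,
the parameters that matter, the numerical choices, and what the shipped
tests do and do not demonstrate.

## Data model

A **compound table** is a tibble with one row per compound: a unique id, a
free-text name, an optional SMILES, a three-valued label (`hepatotoxic`,
`non_hepatotoxic`, `unknown`; file encodings `1/0`, `pos/neg` and spelled-
out labels are all accepted), a provenance tag, and an optional predicted
probability. Structure standardization is deliberately simple and stated:
the deduplication key is the largest dot-separated SMILES fragment with
whitespace removed (`structure_key()`). This is a string-level key — it
strips salts and solvents but will not merge two different valid spellings
of the same molecule. A full canonicalizer can be substituted upstream;
precomputed keys survive the round trip through the CSV reader.

Name matching everywhere in the screening code uses one normalization
(`normalize_name()`): lowercase, trimmed, internal whitespace collapsed,
hyphens mapped to single spaces. It is idempotent, and both sides of every
lookup pass through it, so `"Aloe-Emodin"` and `"aloe emodin"` are the
same ingredient. No fuzzy or synonym matching is attempted — a deliberate
scope boundary, since silent fuzzy hits are worse than documented misses
in a toxicity screen.

## Featurization

Thirteen feature families are registered (`descriptor_families`): twelve
binary fingerprint families (FP, ExtFP, EStateFP, GraphFP, MACCSFP,
PubchemFP, SubFP, SubFPC, KRFP, KRFPC, AP2D, APC2D) and one continuous
family of 2D descriptors. The registry records each family's nominal raw
width and its published widths after all-relevant selection and
correlation pruning on the reference DILI training set; the pruned widths
(which sum to 677) drive the subset-sweep bookkeeping.

The descriptor calculator is a **contract, not a dependency**. Two
backends ship:

* `backend_hashed()` (default): tokenizes the SMILES into atoms, bonds,
  branches and ring closures, enumerates contiguous token n-grams (n ≤ 4,
  a cheap proxy for local substructure paths), and hashes each n-gram into
  the family's nominal bit width with a family-specific salt. The 2D
  family gets ~20 constitutional descriptors (element counts, ring/branch/
  bond counts, approximate molecular weight, composition fractions). The
  backend is deterministic and dependency-free. It does **not** reproduce
  any reference calculator's bit definitions, and the 2D family is far
  narrower than a full descriptor engine's 1444 columns; it exists so that
  every downstream algorithm is exercised end-to-end on real SMILES.
* `backend_precomputed(dir)`: serves per-family CSVs produced by any
  external calculator (the route for reproducing reference results
  bit-for-bit).

Hygiene (`drop_degenerate()`): continuous columns are median-imputed, then
zero-variance columns are dropped. During cross-validation all
preprocessing that learners need (scaling for distance-based learners,
probability calibration) is fitted inside each training fold, so no
information leaks from held-out compounds.

## The selection cascade

**All-relevant selection** (`boruta_select()`) follows the Boruta scheme:
each iteration appends a shuffled shadow copy of every undecided feature,
fits a random-forest importance estimator (ranger, impurity importance,
200 trees by default), and scores a "hit" for each real feature whose
importance beats the *maximum* shadow importance. Decisions use two
one-sided binomial tests on the hit count at `boruta_alpha/2` per tail
(default `alpha` 0.05), Bonferroni-corrected for the initial feature
count. Rejected features leave the candidate pool; features still
undecided at the iteration cap (default 100) stay tentative and are
treated as **not selected** downstream, because the published per-family
counts are single confirmed numbers. Under shuffled labels this procedure
confirms essentially nothing (the test suite checks mean confirmed count
≤ α·p over 50 null permutations).

**Correlation pruning** (`correlation_prune()`) removes features until no
pair exceeds |r| = 0.90 (Pearson), dropping from each offending pair the
member with the larger mean absolute correlation to everything else. The
engine is `caret::findCorrelation(exact = TRUE)` — the same algorithm the
workflow that this package reimplements relied on — behind the package's
own surface, which additionally rejects constant columns with an
instruction to run `drop_degenerate()` first.

**RFE** (`rfe_rank()`) iteratively refits the importance estimator and
removes the least-important feature (step 1) until one survives, yielding
a complete ranking (rank 1 = last survivor). The estimator is seeded per
elimination round, so rankings are reproducible.

**Nested-subset sweep** (`subset_sweep()`): for k = p down to 1, the
learner is cross-validated on the k top-ranked features — exactly p
evaluations — using a *single* stratified fold partition shared across all
k, so that subset sizes are compared on identical splits. The chosen k\*
maximizes `mean(AUC, ACC/100)`; ACC is rescaled to [0, 1] before averaging
because the two metrics are conventionally printed on different scales and
averaging raw values would let ACC dominate by two orders of magnitude.
Ties break toward the smaller subset (parsimony). Per-size learner
failures are recorded in the sweep table rather than aborting the sweep.

## Base learners

Eight algorithms are registered, spanning probabilistic, kernel, instance,
ensemble and tree paradigms. Hyperparameter names follow the conventional
letters: `C` (SVM penalty), `gamma` (RBF width), `K` (neighbors), `B`
(global blending, 0–100), `Depth` (maximum tree depth, 0 = unlimited),
`Cf` (pruning confidence in (0, 1)). Fidelity notes, where this package's
implementation deliberately stands in for a named original:

* `decision_tree` is a pruning-capable CART (rpart) with entropy splits
  standing in for C4.5/J48. The pruning confidence is mapped onto rpart's
  complexity parameter as `cp = 0.04 (1 − Cf)` — monotone in the right
  direction (smaller Cf ⇒ heavier pruning) but not numerically equivalent
  to C4.5's error-based pruning.
* `kstar` is implemented as a distance-weighted instance learner: for each
  query the kernel width interpolates between the nearest-neighbor
  distance (B = 0) and the farthest (B = 100), i.e.
  `b = d_min + (B/100)(d_max − d_min)`, and class probabilities are
  normalized kernel sums. This keeps the defining behavior of the
  entropic blend — B tunes how many instances effectively vote — without
  the original's per-instance entropy optimization.
* `adaboost_tree` is a plain AdaBoost.M1 loop over weighted rpart trees
  (vote weight `log((1−err)/err)`, early stop at err ≥ 0.5); with one
  boosting round it provably equals its base tree, which the tests assert.
* `bagging_knn` bags KNN over bootstrap resamples (10 bags by default)
  and averages the bags' neighbor-vote probabilities.
* `naive_bayes` (e1071) uses Bernoulli likelihoods for binary columns and
  Gaussian for continuous ones, with Laplace smoothing for the former.
* Probability calibration: SVM probabilities come from the standard
  logistic/pairwise-coupling fit on training folds; trees and forests use
  leaf/vote frequencies; distance learners use (weighted) neighbor vote
  fractions. Scores feed both AUC and the decision rule.

The decision rule everywhere is **strict**: a compound is called
hepatotoxic iff its probability exceeds 0.500; exactly 0.500 is negative.
Default tuning grids (used when a single knob is named without a range):
`C ∈ 2^{−5..5}`, `gamma ∈ 2^{−7..3}`, `K ∈ {1,3,5,7,9}`,
`Cf ∈ {0.1,0.25,0.5}`, `Depth ∈ {0,5,10,20}`, `B ∈ {1,20,40}`; grids are
scored by the same `mean(AUC, ACC/100)` under stratified CV.

## The combined classifier

Each base learner contributes its best (family, subset) model; the bases'
**hard** 0/1 predictions — not probabilities — form an n × k binary
meta-feature matrix, and a Bernoulli Naive Bayes with Laplace(+1)
likelihood smoothing and unsmoothed class priors is fitted on it. The
meta-model is an explicit closed form (`theta[j,c] = (n_{1,c}+1)/(n_c+2)`)
so its posteriors are hand-checkable, and with k binary features zero
counts inside folds are inevitable, which the +1 smoothing absorbs.

Where the meta-features for *training* compounds come from is a genuinely
open design point: the classical combined-classifier description has the
final bases predict their own training set (resubstitution), which leaks
optimistic meta-features; cross-fitted (out-of-fold) meta-features are the
statistically safer choice. Both modes are implemented;
**out_of_fold is the default**, and `resubstitution` is provided for
fidelity with the classical description. Reports record the mode. The base
count is not hard-coded: the reference configuration uses eight bases
(one per algorithm), while unit tests exercise reduced stacks and stub
bases that replay fixed truth tables, isolating the meta-learner.

A reference majority-vote fusion (`majority_vote()`) exists for
comparison and tests only.

## Evaluation

Metrics come from the **pooled** confusion matrix over all CV folds (one
matrix, not per-fold averages), matching the summary convention of the
classical data-mining toolkits. ACC is reported on the 0–100 scale; SE,
SP, BACC and AUC on 0–1. BACC is computed pre-rounding as (SE+SP)/2.
Display rounding is **half away from zero** to three decimals — this is
what makes (0.725 + 0.720)/2 = 0.7225 display as 0.723 and
(0.813 + 0.750)/2 = 0.7815 as 0.782; banker's rounding would print 0.722
and 0.782 inconsistently. Internal values keep full precision.

AUC uses the rank (Wilcoxon) statistic with half-weighted ties, which
equals trapezoidal integration of the full-threshold ROC sweep and is
invariant under strictly increasing score transforms (both properties are
asserted in tests, with an independent ROC package as cross-check).

Cross-validation is stratified, seeded, and recorded: every compound is
predicted exactly once by a model that never saw it. **Y-randomization**
permutes labels uniformly (class counts preserved exactly), re-runs the
entire cross-validated pipeline per permutation (default 100 runs), and
reports the accuracy distribution; on balanced data the mean must sit at
the majority-class rate. External evaluation checks
training/external disjointness by compound id and reports violations
(warning, or error in strict mode) alongside the metrics.

## The screening procedure

Three channels, integrated by union with provenance:

1. **Classifier**: featurizable ingredients are scored by the combined
   classifier; strict probability > 0.500 admits an ingredient.
   Structure-less ingredients (common for large glycosides) are excluded
   from this channel with an explicit notice — channels 2–3 still cover
   them, which is precisely the argument for a multi-channel screen.
2. **HILI list**: exact intersection of normalized ingredient names with
   a curated herb-induced liver injury reference set.
3. **Network**: neighbors of the herb node in a bipartite
   herb–hepatotoxic-ingredient network (queries normalized; an absent
   herb yields an empty set plus a notice, not an error).

`integrate_subgroups()` is commutative and idempotent in its set
arguments and reports per-ingredient provenance plus each channel's
unique contribution. The shipped He Shou Wu fixture encodes the published
channel memberships (21/6/7, union 25, uniques 15/1/3) as a regression
test; its subgroup-1 set is fixed rather than recomputed, since
recomputing it would require the original training compounds.

Ingredient spectra can be clustered (`cluster_ingredients()`) by
agglomerative clustering on Euclidean distance. The linkage is a recorded
parameter defaulting to **average** — the distance metric is fixed by the
procedure, the linkage is not, so claims about a particular number of
clusters depend on it and are deliberately not asserted in tests.

## Synthetic data: what it shows and what it cannot

`make_classification_set()` plants the statistical structure the cascade
assumes: informative features separated between classes by `effect_size`
(mean shift in SD units for continuous features; bit-probability gap for
binary ones), redundant features built as parent + calibrated noise
(`sigma = sqrt(1/rho^2 − 1)` for continuous, flip probability `(1−rho)/2`
for binary) to land at the target correlation, and label-independent
noise. Defaults — n = 200, 5 informative / 0 redundant / 10 noise,
balance 0.5, effect 1.5 SD (continuous) or 0.6 gap (binary), rho 0.95 —
were fixed once as a regime where a competent selector should succeed
decisively: effect 1.5 gives single-feature AUC ≈ 0.86, strong but not
degenerate, and rho 0.95 straddles the 0.90 pruning cutoff from above.
Generation is byte-deterministic given the spec.

Passing tests on this generator demonstrate algorithmic correctness —
selector calibration, ranking recovery, fold hygiene, fusion arithmetic —
under clean, independent, homoscedastic features. They do **not**
demonstrate performance on real chemistry: real fingerprints are sparse,
blockwise-dependent, and their class signal is diffuse across many weak
bits. Claims about real-data accuracy require the real training table
(see `reproduce_training_cv()`).

Test and acceptance problem sizes (n = 60–200 compounds, ≤ 21 features,
5-fold CV, 20–50 property replicates) are the package's chosen desk scale:
large enough for the asserted statistical properties to have comfortable
margins, small enough that the full suite runs in well under a minute.

## Numerical choices and degenerate inputs

* Ties in the subset sweep and tuning: smaller k / earlier grid row.
* RFE importance ties: the first minimal-importance column is dropped
  (fixed column order ⇒ deterministic).
* Probability exactly at the threshold: negative (strict inequality).
* Constant columns: rejected by `correlation_prune()` (callers must run
  `drop_degenerate()`), tolerated by learners via per-fold scaling with
  unit fallback for zero-SD columns.
* Zero counts in the meta NB: absorbed by Laplace(+1) smoothing.
* Gaussian NB zero-variance cells: guarded by the predictor's density
  floor.
* Empty classes in a confusion matrix: an error naming the missing class,
  never NaN metrics.
* A correlation *pattern* requested in tests must be realizable (positive
  semi-definite); the pruning tests therefore use the nearest feasible
  configurations of their target correlations.

## Command-line surface and configuration

`run_config()` merges a YAML file or list over package defaults and
rejects unknown keys; every pipeline run writes its resolved configuration
next to its outputs, and identical resolved configurations (same seed)
produce byte-identical metric reports. The Rscript wrapper
(`inst/cli/hepascreen`) exposes `pipeline`, `screen` and `synth`
subcommands with exit codes 0 (success), 2 (configuration), 3 (data),
4 (modeling). Finer-grained stage subcommands were not added: each stage
is an exported function, and R scripts compose them more flexibly than a
CLI matrix would.

## Known limitations

* The hashed featurizer is a structural proxy, not a reference descriptor
  implementation; absolute accuracies on real compounds depend on the
  backend supplied.
* Fitted models are session objects; persistence beyond the pipeline's
  text reports (config, sweep tables, metrics, predictions) is not
  provided.
* The K* and J48 stand-ins match behavior contracts, not the originals'
  internals; published per-learner numbers obtained with those originals
  will differ in detail.
* No applicability-domain estimation, no confidence intervals beyond the
  Y-randomization spread, no fuzzy name resolution, no absorption/ADME
  filtering.
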