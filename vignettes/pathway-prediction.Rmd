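---
title: "Pairwise compound-pathway association prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise compound-pathway association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpred)
```

## The problem and the model

Pathway knowledge bases organize pathways hierarchically: top categories
(L1, e.g. metabolism), subcategories (L2, e.g. carbohydrate metabolism) and
individual pathways (L3, e.g. glycolysis). Compounds carry annotations to
some of these pathways, and the prediction task is to supply the missing
ones. `pathpred` frames this as binary classification of *(compound,
pathway)* pairs: the feature vector of a pair is the concatenation of a
compound representation and a pathway representation, and the label says
whether the compound is associated with that pathway. A single model
therefore predicts for every pathway at every level, and pathways with few
compounds benefit from parameters shared with the rest of the hierarchy.

### Compound representation: atom-coloring counts

Molecules are heavy-atom graphs parsed from CTAB V2000 molfiles (V3000 is
rejected; formal charges come from `M  CHG` property lines; disconnected
fragments such as salt components are kept). An atom's *depth-0 color* is
its element symbol, suffixed with the formal charge when nonzero (`"N+1"`).
Its *depth-d color* is its depth-(d−1) color followed by the
lexicographically sorted list of `(bond order : neighbor depth-(d−1) color)`
pairs. This is iterative neighborhood refinement in the Morgan /
Weisfeiler–Lehman family: two atoms get the same depth-d color exactly when
their rooted neighborhoods of radius d are isomorphic (element, bond order
and topology), which the test suite verifies against an independently coded
rooted-subtree canonicalization and under random atom relabelings.

A compound's feature vector counts every color it contains across all depths
0..D. An atom contributes a new color at depth d only while its color string
is still changing, so stabilized environments are not double-counted. With
`max_depth = "auto"`, D is the first depth at which the partition of atoms
into color classes stops refining — the Weisfeiler–Lehman fixpoint, at most
n−1 iterations. Aromatic bonds written as type 4 are kept as a distinct
order with no kekulization or normalization, and no fragment selection is
applied; hydrogens are removed before coloring, so colors never mention H
and compound *size* equals the atom count of the colored graph.

The vocabulary — the sorted union of all colors across the corpus — is built
once from the full compound set *before* any train/test splitting. Feature
definitions therefore see all compounds; this mirrors the upstream
protocol, and the de-duplication step below exists precisely to limit the
resulting leakage. Sorting uses byte (radix) order, making the vocabulary
independent of locale and of compound order; colors met at prediction time
that are missing from the vocabulary are dropped with a warning.

### Pathway representation and the hierarchy

Direct annotations (usually to L3, occasionally to L2) are propagated
upward: the expanded annotation set of a compound is closed under taking
parents. A pathway's feature vector is the element-wise *sum* of the feature
vectors of its member compounds under the expanded map. Summation is chosen
over averaging or binarization for consistency with the additive definition
of pathway size (the summed non-hydrogen atom counts of member compounds)
and because downstream reporting uses positive-count features; it is an
assumption of this implementation, not a certified property of the upstream
pipeline. The pathway feature space is the compound vocabulary restricted to
colors positive in at least one pathway, which is why its dimension is
smaller than the compound dimension. Pathways with no member compounds
cannot be represented and are excluded with a warning.

### The pair dataset

Duplicate compound feature vectors, and duplicate pathway feature vectors,
are removed before the cross-join (keeping the lexicographically smallest
id), because two entities with identical features place effectively the same
entry in both training and test folds. After de-duplication the cross-join
has `n_c × n_p` conceptual entries; entry k maps to compound
`(k−1) div n_p + 1` and pathway `(k−1) mod n_p + 1`, and the concatenated
table is never materialized — batches are gathered blockwise from the two
matrices, bit-identically to one-at-a-time assembly (a tested contract).
Datasets can be filtered by compound size, by pathway size (the canonical
20-threshold grid `pathway_filter_grid()` runs 5..50 by 5, 50..100 by 10,
100..200 by 20) and by hierarchy level; filtering pathways never touches
compounds.

The on-disk container is a plain-text directory: MatrixMarket files for the
two sparse count matrices, TSVs for entities, labels (0-based index pairs)
and the hierarchy, plus a JSON manifest.

### Classifier

The classifier is a multi-layer perceptron over raw concatenated counts
(no scaling or normalization — the upstream protocol mentions none): ReLU
hidden layers with inverted dropout, a single sigmoid output, binary
cross-entropy loss, Adam updates with decoupled (learning-rate-scaled)
weight decay, seeded shuffling and initialization. Training is exactly
reproducible given the configuration, and the training RNG never disturbs
the caller's stream.

Tunable parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `hidden_sizes` | 64, 32 | ample capacity for desk-scale feature spaces; scale up (e.g. 512, 128) for KEGG-scale inputs of ~28k dimensions |
| `dropout` | 0.1 | mild stochastic regularization on hidden units |
| `learning_rate` | 3e-3 | Adam step; converges on count-scale inputs within a few hundred epochs |
| `weight_decay` | 0.1 | decoupled decay (effective shrink = lr × wd per step); discourages high-norm memorization while leaving low-norm class rules intact |
| `batch_size` | 256 | a few gradient steps per epoch at desk scale |
| `max_epochs` / `patience` | 400 / 40 | early stop on a training-loss plateau (relative tolerance 1e-4) |
| `threshold` | 0.5 | probability ≥ threshold is called positive (boundary inclusive) |

The upstream study tuned its hyperparameters with a dedicated search but did
not report the chosen values, so exact reproduction of its headline CV
scores is not an implementation target; the defaults above are declared,
configurable, and sized for the synthetic study conditions described next.

### Cross-validation and metrics

`run_cv()` repeats stratified entry-level train/test splits (stratification
on the binary label only; test fraction defaults to 0.1 — the upstream
protocol states neither the key nor the ratio, so both are configurable).
Iteration i derives its split seed and training seed from `base_seed + i`.
Overall confusion counts are stored per iteration — their per-iteration
metrics aggregate to mean/median/sd — while per-compound and per-pathway
counts accumulate *across* iterations so that individual entities
accumulate enough test appearances for defined metrics. The MCC denominator
is evaluated in log space because the product of the four marginals
overflows 64-bit integers at knowledge-base scale (tens of millions of true
negatives); the numerator's products stay below 2^53 and are exact in
doubles. A metric whose denominator is zero is reported as `NA` (null) and
excluded from aggregation and correlation — never coerced to 0. Group
reports sum counts within hierarchy levels or L1 subtrees (the L1 itself
included) before deriving metrics, and `size_mcc_correlation()` computes a
Pearson correlation with a two-sided t-test p-value (the test family used
for the published correlation table is unstated; the t-test is this
package's declared choice).

Entry-level splitting is deliberately replicated from the upstream
protocol: the same compound appears in training and test entries (paired
with different pathways). Group-aware (compound-level) splitting would
prevent this leakage but would change the estimand; see the caveats below.

## The synthetic data generator

`generate_dataset()` emulates the real inputs without any download:

* **Molecules.** Size is uniform on `size_range` (default 4–25 heavy atoms,
  a compromise between the right-skewed knowledge-base size distribution and
  desk-scale compute). The graph is a uniform random tree plus up to two
  ring-closing edges; bond orders are drawn from {1, 2}; molfiles are valid
  V2000 text that round-trips through the parser.
* **Classes.** Each compound belongs to one of `n_classes` latent classes
  (default: one per L3 pathway). A class has a signature ordered element
  pair; its molecules contain exactly ~60% of the main element and ~30% of
  the secondary (largest-remainder rounding, random atom order, remainder
  spread round-robin). Compositions are therefore *exact*, so classes are
  separable from depth-0 colors at every size ≥ 3 — the planted signal does
  not depend on the coloring depth. Two hundred compounds over twelve
  classes at sizes 4–25 produce duplicate composition vectors, which the
  pipeline's de-duplication then removes (about a third at depth 0); this
  exercises the same duplicate-removal path the real data needs.
* **Hierarchy.** Defaults to 4 L1 / 6 L2 / 12 L3 (~20 pathways). Each level
  is attached to the one above with guaranteed coverage (the first children
  spread over distinct parents, the rest at random).
* **Annotations.** Each L3 pathway prefers one class. A compound draws an
  *effective class* — its own with probability `2·(class_purity − 0.5)`,
  otherwise uniform over all classes — and is annotated to the L3 pathway(s)
  of that effective class, occasionally (p = 0.1) adding the parent L2
  directly, which is redundant after propagation but exercises the
  direct-L2 code path. `class_purity = 1` therefore plants a noise-free,
  deterministic class→pathway rule; `class_purity = 0.5` makes annotations
  independent of composition (no signal at all). Rates above
  `annotation_rate = 1` add Poisson-distributed random extra annotations
  that are unpredictable by construction, emulating genuinely multi-pathway
  compounds.

With the defaults, a compound is positive for its L3 pathway plus that
pathway's L2 and L1 ancestors: about 3 of ~20 pathways, a positive fraction
of roughly 13% — imbalanced in the same direction as the real cross-join.

### Why the hierarchy shape matters for the null control

The generator must satisfy two endpoint contracts: at `class_purity = 1` the
pipeline should recover the planted signal almost perfectly, and at 0.5 a
trained model should do no better than chance. The second contract
constrains the *dataset*, not just the model: if any pathway's positive rate
exceeds the 0.5 decision threshold, a model that learns nothing about
compounds still scores well by reproducing pathway base rates. With only two
L1 categories each L1 row sits near 50% positives and this marginal
predictor alone reaches an MCC of ~0.4 on signal-free data. The default
hierarchy (4 L1) keeps every pathway's positive rate at or below ~1/4, so on
signal-free data the fitted classifier's probabilities all fall below
threshold and it predicts no positives — the MCC is then *undefined* (all
four marginals cannot be positive), which is the degenerate "no signal"
outcome, reported as null exactly as rarely-predicted pathways are in the
real study.

### What the planted-signal demonstration does and does not show

The end-to-end property tests (and the corresponding acceptance checks) run
the full pipeline — molfiles → coloring → de-dup → propagation → cross-join
→ stratified CV → MLP — at coloring depth 0 and verify held-out MCC ≥ 0.9
under the pure planted signal and a null result (undefined MCC or |MCC| <
0.1) under `class_purity = 0.5`, across three seeds each. Depth 0 is used
deliberately. At depth ≥ 1 the compound feature dimension exceeds the number
of compounds, so *any* labeling — including the null's random one — is
linearly separable from the compound identity, and the entry-level split
lets a sufficiently trained network memorize per-compound labels and carry
them to test entries of the same compound. That leak is a property of the
replicated evaluation protocol, and the planted signal was put in element
composition precisely so that the recovery property is insensitive to the
depth choice. Consequently these tests demonstrate correct plumbing and
signal recovery under the stated conditions on synthetic data; they say
nothing about absolute performance on real knowledge-base data, where
features are richer, annotations are noisy and multi-pathway, class
imbalance is more extreme (one top category holds most positives), and some
measured skill reflects the same entry-level compound leakage.

Other features of real data the generator does not emulate: chemically
realistic valences and aromatic systems (type-4 bonds appear only in parser
fixtures), the exact right-skew of the size distribution, compounds
annotated across unrelated subtrees, and feature dimensions in the tens of
thousands.

## Numerical and degenerate-input choices

* MCC: log-space denominator; `NA` when any marginal is zero; numerator
  exact in doubles up to counts of ~10^8.
* De-duplication ties break to the lexicographically smallest id; the
  removal report lists (removed, kept) pairs; the operation is idempotent.
* Stratified splits use exact per-stratum rounding, so a 10-positive,
  100-entry dataset at test fraction 0.2 places exactly 2 positives in the
  test fold; degenerate requests (empty side, single-class data) error.
* Empty molecules, all-hydrogen molecules, molfiles whose counts line
  disagrees with the atom block, V3000 input, bonds out of range, unknown
  pathway ids in annotations, and filters that empty the dataset all raise
  immediate, specific errors.
* An untrained network (`max_epochs = 0`) predicts ~0.5 everywhere; the
  probability-equals-threshold boundary classifies as positive.
* Problem sizes in the shipped tests: 20–200 compounds, ~20 pathways, up to
  ~2,100 pair entries and a few hundred training epochs; the count-identity
  checks build 6,485 × 502 datasets (3.26M conceptual entries) without
  materializing them.

## Known limitations

* The pathway aggregation function (sum) and the pathway-vocabulary
  restriction are declared assumptions where the upstream description is
  silent.
* Vocabulary construction before splitting leaks feature definitions across
  folds, as in the upstream protocol.
* Entry-level stratified splitting leaks compound (and pathway) identity
  between folds; per-compound metrics on real data are optimistic to an
  unquantified degree.
* The MLP trainer is plain R matrix arithmetic: adequate at desk scale,
  not a GPU data-loading benchmark; nothing here measures the upstream
  study's throughput claims.
* Undefined (null) metrics are excluded from aggregates rather than
  imputed; their counts still contribute to pooled group sums.
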