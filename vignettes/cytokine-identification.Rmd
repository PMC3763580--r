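---
title: "Identifying cytokines from sequence: features, resampling, and the selective ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cytokines from sequence: features, resampling, and the selective ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosel)
```

Cytokines — the secreted signalling proteins of the immune system — are a
classic needle-in-a-haystack classification target: among all protein
families, only a tiny fraction are cytokine families, and sequence
similarity alone does not find them (many cytokines share little primary
sequence). `cytosel` frames the problem as binary classification from
primary sequence alone and implements the three ingredients that make it
workable: physicochemical sequence features, hybrid rebalancing of an
extremely imbalanced training set, and a selective voting ensemble. This
vignette explains each stage, the assumptions behind it, and the design
choices we made where more than one defensible option existed.

## Sequence features

A protein is modelled as a string $S = R_1 R_2 \dots R_L$ over the
20-letter amino-acid alphabet. Four feature families are computed, all
bounded in $[0, 1]$:

* **Composition** (20 features): residue frequencies $n_i / L$.
* **Group content** (24): for each of 8 physicochemical properties, the
  alphabet is partitioned into 3 groups, and the feature is the fraction
  of residues in each group. Because the groups partition the alphabet,
  each property's triple sums to 1.
* **Bivalent transition frequency** (24): for each property and each
  unordered group pair, the number of adjacent residue pairs whose
  members fall in the two groups (in either order), divided by $L$.
* **Distribution** (120): for each property and group, the 1-based
  position of the first, 25%, 50%, 75% and 100% occurrence of a group
  member, divided by $L$. With $n_g$ occurrences, the $q$-quantile
  occurrence is the $\lceil q\, n_g \rceil$-th one.

The 120-dimensional distribution family is the core classification set;
concatenating all four (composition, content, transition, distribution —
in that order) gives the full 188-dimensional set.

The eight properties are secondary structure, solvent accessibility,
normalized Van der Waals volume, hydrophobicity, charge, polarizability,
polarity, and surface tension. The three-group memberships ship as a
YAML table (`inst/extdata/property_groups.yaml`) following the canonical
divisions of the feature-extraction literature, anchored to the
secondary-structure helix group $\{E,A,L,M,Q,K,R,H\}$. The table is
data, not code: users with a different division scheme pass their own
file to `read_property_groups()`, and all feature indices follow the
file's property and group order.

### Numerical conventions

Several corner cases are not fixed by the formulas and were pinned down
as follows:

* **Quantile index rule.** $k = \lceil q\, n_g\rceil$ with 1-based
  positions. This makes $q = 1$ pick exactly the last occurrence and
  $q = 0.25$ coincide with the first occurrence whenever $n_g \le 4$,
  consistent with the "first, 25%, …, 100%" progression.
* **Absent groups.** If a group has no member in the sequence, its five
  distribution features are 0 — the only constant that stays inside
  $[0,1]$ without inventing a position.
* **Transition denominator.** Transitions are divided by $L$, not
  $L - 1$. Some feature-extraction variants use $L-1$ (the number of
  adjacent pairs); we keep $L$ and document it so users comparing
  against other implementations can reconcile a factor of $(L-1)/L$.
* **Single-residue sequences.** No adjacent pairs exist; all transition
  features are 0 and a warning is raised.
* **Ambiguous residues** (B, J, O, U, X, Z) are rejected in strict mode
  and dropped (with a warning, shrinking $L$) in lenient mode, because
  every formula above is defined only over the 20 canonical letters.

## Hybrid resampling

Realistic training sets are extremely imbalanced (on the order of one
positive per 40–100 negatives). Training directly on such data produces
a classifier that is almost always right by always saying "negative":
overall accuracy then approximately equals specificity while sensitivity
— the thing we care about — collapses. The package therefore reports the
geometric mean $GM = \sqrt{SN \cdot SP}$ as the headline metric: it is
near zero whenever either class is neglected.

`hybrid_resample()` rebalances with two complementary moves:

* **SMOTE oversampling** of the minority class: each synthetic sample is
  $x + u (x_{nn} - x)$ with $u \sim U[0,1]$, $x$ a random real minority
  row and $x_{nn}$ one of its $k$ nearest minority neighbours (default
  $k = 5$). Synthetic points stay on segments between close real
  positives, so the minority manifold is thickened rather than distorted.
* **K-means cluster undersampling** of the majority class: the majority
  rows are clustered into exactly `majority_target` clusters and each
  cluster contributes its member closest to the centroid. Every kept row
  is a verbatim input row, and coverage of the majority distribution is
  preserved — unlike uniform subsampling, which can drop whole regions.

Oversampling alone at 1:84 would manufacture a mostly synthetic
training set; undersampling alone would throw away almost all majority
information. The defaults (`minority_target = majority_target = 2000`)
echo a rebuilt training set of roughly two thousand rows per class.

### K-means details

The undersampler's K-means is implemented in-package because its exact
behaviour is part of the method's contract: squared-Euclidean
assignment with ties to the lowest cluster index, at most
`kmeans_iter` Lloyd iterations, an emptied cluster re-seeded with the
point farthest from its centroid, and full determinism given the plan
seed. Initial centres are chosen by seeded K-means++ ($D^2$-weighted)
sampling of input rows rather than uniform sampling: with uniform
seeding, well-separated majority clusters are frequently missed (two
seeds land in one cluster, none in another, and Lloyd cannot recover),
which violates the coverage property the undersampler exists to
provide. K-means++ keeps the guarantee practical while remaining fully
seeded. The same routine clusters classifier correctness patterns in
the ensemble (below). A cluster-count fraction for the initial
centroids appears in some descriptions of this undersampling scheme as
a separate tunable; under the representative-per-cluster reading used
here it coincides with the target size, so the plan exposes only
`majority_target`.

## The selective ensemble

Eighteen heterogeneous base learners are fitted: linear and RBF margin
classifiers, logistic regression, 1/5/10-nearest-neighbour, four tree
variants (CART, an information-gain C4.5-style tree, a depth-4 pruned
tree, a single random tree), a random forest, naive Bayes, a decision
stump, a single-feature threshold rule, a depth-2 rule-table stand-in,
a penalised depth-2 conjunctive-rule stand-in, a ridge-regularised
logistic model, and a constant majority-class baseline. The pool is
deliberately diverse; individual weakness is acceptable.

Each learner's **correctness pattern** is recorded as a binary result
matrix $R_{ij} = 1$ iff learner $i$ classified sample $j$ correctly. By
default these flags come from internal 5-fold out-of-fold predictions:
resubstitution scoring would credit memorising learners (1-NN scores a
perfect row on its own training set) and bias the committee toward
overfitters. A `mode = "resubstitution"` switch restores the literal
fit-and-score-on-the-same-samples behaviour for comparison.

The rows of $R$ are clustered ($K = 9$ by default, capped at the pool
size) so that learners that err on the same samples share a cluster.
The most accurate learner of each cluster is nominated, and the
committee is grown by **circulating forward selection**: candidates are
scanned in descending accuracy order, and a candidate joins only if it
*strictly increases* the committee's majority-vote accuracy **and**
*strictly decreases* the committee's mean pairwise agreement (the
fraction of samples on which two members' correctness flags coincide).
The double condition admits only learners that are both helpful and
complementary; a clone of an existing member can never join. Scans
circulate until the committee accuracy reaches the current target
(initially 1); an unmet target is relaxed by 0.05 and the circulation
resumes, stopping once the target falls below the best accuracy
achieved or no candidates remain.

Diversity is not uniquely defined in the ensemble literature; mean
pairwise agreement was chosen because "agreement declines" is exactly
the reading under which the add-rule promotes complementary error
profiles, and the implementation keeps it in one small function
(`mean_pairwise_agreement`) so a kappa-style statistic can be swapped
in.

Prediction is by majority vote of the committee; the share of members
voting positive is exposed as `vote_fraction`, a usable prediction
probability. An even split follows the most accurate member. For binary
labels, a committee member that is wrong necessarily votes for the
other class, so committee accuracy can be computed from $R$ alone by
counting correct members per sample — the property the selection loop
exploits.

## Evaluation protocol

`crossvalidate()` uses stratified folds (default 10; every class must
have at least one member per fold) and pools held-out predictions into
a single confusion matrix with a per-fold breakdown. Crucially, any
resampling configured in the pipeline runs **inside each training fold
only**. Resampling the full dataset before cross-validation leaks
information: synthetic copies of a test sample's neighbours appear in
training folds, and undersampling sees the test distribution. The
leak-free protocol is the package default; the literal
resample-then-validate order can still be reproduced by calling
`hybrid_resample()` first and cross-validating the result without a
plan, which is how the rebuilt-training-set numbers reported by
`scripts/acceptance.R` under `sampled` should be read when comparing
protocols.

## The synthetic-sequence generator

`generate_sequences()` produces negatives i.i.d. uniform over the
alphabet and positives with excess probability mass `bias` on a chosen
residue set (default: the helix group), lengths uniform on
`length_range`. It targets exactly one thing: classes that differ in
residue-group usage, so the feature extractor separates them and the
whole pipeline is exercisable without external data. It does **not**
emulate motifs, domains, phylogenetic correlation, or real length
distributions — so green tests demonstrate the machinery, not
biological performance.

One property of the generator matters for interpreting results: for
i.i.d. residues, the position of the $\lceil q\,n_g\rceil$-th
occurrence of a group concentrates near $q \cdot L$ *regardless of the
group's frequency*. The 25/50/75/100% distribution features are
therefore nearly class-independent under this generator, and only the
first-occurrence features (and boundary effects in the tails) carry
signal in the 120D set. Group bias is instead encoded directly — and
strongly — in the content features. Consequently, on this generator the
full 188D set separates the classes essentially perfectly while the
120D distribution core supports only moderate geometric means, a
ranking that says more about i.i.d. sequences than about the feature
families: on real proteins, positional structure is exactly what the
distribution features exist to capture.

The desk-scale experiment in `scripts/acceptance.R` and the acceptance
test uses 25 positives vs 1000 negatives (1:40), bias 0.5, lengths
50–200, 5-fold cross-validation, and in-fold resampling targets of
150/150 — sizes chosen so the complete experiment runs in about two
minutes while keeping at least 20 real positives in every training
fold (the SMOTE neighbour count must stay below the real minority
count). On the 120D core the unsampled run shows the canonical
imbalance signature (accuracy ≈ specificity while GM collapses toward
0) and in-fold resampling recovers sensitivity; the numbers themselves
are computed fresh by the script on every run.

## Known limitations

* The base-learner pool approximates a historically motivated mix of
  algorithms with their closest R equivalents; a few exotic members
  (rule tables, conjunctive rules, functional trees) are stood in for
  by behaviourally similar models, and no attempt is made to match any
  other toolkit's numeric output learner-for-learner.
* Committee selection optimises training-set (out-of-fold) accuracy;
  with very small minority classes the resampled training folds contain
  SMOTE-interpolated points whose out-of-fold predictions are easier
  than fresh data, so committee accuracy overestimates held-out
  performance. The cross-validation harness exists precisely to measure
  the honest number.
* Dataset curation implements the longest-per-family and
  excluded-family rules only; similarity-based redundancy reduction
  (CD-HIT-style clustering at an identity threshold) is out of scope
  and should be applied upstream if needed.
* The package is binary (cytokine vs. not); multiclass family
  assignment is out of scope.
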