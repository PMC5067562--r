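---
title: "Methods: data-driven stratification of item-level task performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven stratification of item-level task performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`eyestrat` stratifies a cohort of subjects into subgroups from binary
item-level performance on a fixed task (the motivating case is the
36-item, four-alternative Reading the Mind in the Eyes Test). The input
is a subjects-by-items matrix of correct/incorrect indicators; timed-out
items are scored incorrect, and subjects who timed out on 9 or more of
36 items are excluded beforehand (`filter_timeouts()`), since their
patterns reflect non-response rather than ability.

The stratification itself is a similarity-network pipeline:

* **Hamming distance** between subjects' response vectors — the natural
  metric for binary data, interpretable as the percentage of items on
  which two subjects disagree.
* **Topological overlap (TOM)** of the adjacency `a = 1 − d`. TOM
  rewards pairs that agree with each other *and* with the same third
  parties, averaging the pairwise noise of a 36-item comparison over the
  whole cohort's neighborhood structure. We use the standard unsigned
  form with unit diagonal; the adjacency and connectivities are retained
  on the result for audit. No soft-thresholding power transform is
  applied: the adjacency enters as `1 − d`, and `1 − TOM` is the
  dissimilarity passed on to clustering.
* **Ward linkage** on `1 − TOM`, computed by the Lance–Williams
  recurrence applied directly to the supplied dissimilarity (the
  historical non-squared dialect, `stats::hclust(method = "ward.D")`).
  The squared variant (`ward.D2`) is exposed via `squared = TRUE`. The
  test suite cross-checks the tree against an independent step-by-step
  implementation of the recurrence.
* **Dynamic hybrid tree cut** — branch-specific cut heights instead of
  one global height; described below.
* **Rank ordering** of the resulting clusters by mean total score, so
  that subgroup 1 is always the lowest-performing subgroup. Rank, not
  cluster identity, is what can be compared across independently
  clustered cohorts ("homologous" labels); labels are never transferred
  between cohorts directly.

Every stage is deterministic given its input; `stratify_cohort()`
records its parameters (and an optional seed for provenance) on the
returned assignment.

## The dynamic hybrid tree cut

`cut_tree_dynamic()` is authored in this package. Working top-down from
the root, a split into two child branches is accepted when each child of
at least `min_cluster_size` elements is

* **internally tight**: its *core scatter* — the mean merge height
  inside the branch — is at most `max_core_scatter` of the parent's
  merge height, and
* **well separated**: the *gap* between the parent's merge height and
  the child's own top merge is at least `min_gap` of the parent height.

Both criteria are ratios to the parent height, which makes them
scale-free across the depth of the tree. When one child qualifies and
its sibling is a small offshoot (fewer than `min_cluster_size`
elements), the offshoot's elements are set aside as outliers and the
eligible child is descended further; when neither child qualifies, the
node becomes a terminal cluster. If no split is ever accepted, the whole
tree is one cluster — in particular, a tree whose merges all occur at
one height (all pairwise dissimilarities equal) yields a single cluster.

The `deep_split` parameter (0–4, default 1) interpolates
`max_core_scatter` over `c(0.40, 0.55, 0.70, 0.80, 0.90)` with
`min_gap = (1 − max_core_scatter) × 0.45`: higher values tolerate more
within-branch scatter and demand smaller gaps, hence split more finely.
These constants are the package's own calibration, fixed by the
planted-partition recovery suite (two planted blocks recovered exactly;
five graded blocks recovered with adjusted Rand index ≥ 0.9; pure-noise
and equal-dissimilarity inputs left as one cluster; cluster count
monotone in `deep_split`). Fidelity to the published lineage of this
algorithm is behavioral — partition recovery — not bit-exact agreement
with any specific prior implementation.

Outlier assignment (the hybrid step, `assign_outliers = TRUE`) gives
every unassigned element to the cluster with the smallest mean
dissimilarity, provided that mean is within the cluster's admission
radius, defined as the largest mean within-cluster dissimilarity of any
current member. Elements outside every radius stay labelled 0.

Tie-breaking is lowest-index-first throughout (class argmax in
prediction, original-label order in rank ordering), so identical inputs
give identical outputs.

## Subgroup characterization

* `effect_size_grid()` compares every subgroup of one assignment with
  every subgroup of another (e.g. ASC versus TD within a cohort) by
  pooled-variance Student *t*-tests — chosen to match the pooled-SD
  Cohen's *d*; Welch is an option — with Bonferroni correction at family
  size `K_A × K_B` (20 for a 5 × 4 grid). The *d* sign convention is
  fixed: first assignment minus second. Cells with a subgroup below 2
  subjects are flagged untestable rather than dropped, keeping the grid
  shape stable. Within-group grids (ASC vs ASC) are not computed by the
  pipeline: selecting and testing subgroups on the same scores would be
  circular.
* **Covariate control** (e.g. verbal IQ): scores of all subjects from
  both assignments are residualized on the covariate by least squares
  before testing. This is the simplest defensible reading of
  "controlling for" a nuisance variable; adjusted results should be
  read alongside unadjusted ones.
* `split_items()` runs the identical pipeline along the item axis and
  takes the tree's top split as the easy/difficult partition, labelling
  as easy the set with the higher overall percent-correct.
* `item_difficulty()` is the percentage of a subgroup answering each
  item correctly; `difficulty_correlations()` correlates subgroup
  profiles (Pearson by default, Spearman optional) over the easy or
  difficult subset, with Benjamini–Hochberg FDR flags at `q = 0.05`
  (`bh_fdr()`, cross-checked in tests against a brute-force step-up).
* `cross_cohort_dissimilarity()` concatenates cohorts in subgroup rank
  order and returns the full Hamming matrix plus a block index, the
  descriptive view of within- versus between-subgroup homogeneity
  across cohorts.
* `phenotype_tests()` runs one-way ANOVA, Kruskal–Wallis (for skewed
  questionnaire scores), or chi-square against expected counts (sex
  ratios) per variable, with Bonferroni-corrected pairwise post-hocs for
  significant omnibus tests. When all observations are tied the
  Kruskal–Wallis statistic is reported as 0 (the tie-correction
  denominator degenerates). Missing phenotype values are excluded per
  test, never imputed.

## Cross-cohort classification

`adaboost_m2()` implements AdaBoost.M2 boosting over (example,
incorrect-label) pairs with weighted linear discriminant weak learners.
Binary item features make the pooled covariance singular, so the
discriminant is ridge-regularized with `λ = 10⁻³ × trace/dimension`;
class plausibilities are softmax posteriors in [0, 1]. Pseudo-loss,
`β_t = ε_t/(1 − ε_t)` and the weight update follow the standard
formulation; boosting stops early at `ε_t ≥ ½` or `ε_t = 0`, with β
bounded below by 10⁻¹⁰ so learner weights stay finite. Default 20
rounds. The exact regularization of the historical implementations this
mirrors is unknown; the fidelity target is behavioral — above-chance
cross-cohort transfer — not numeric parity.

`permutation_test()` refits the full ensemble for every one of the
`n_perm` label permutations (default 10,000; a flag, so tests scale it
down) rather than permuting scores, and reports the add-one p-value
`(1 + #{null ≥ observed}) / (1 + n_perm)` — a valid p-value that can
never be exactly zero from finite permutations — alongside the raw
proportion. The seed fully determines the permutation stream.
`evaluate_predictions()` adds confusion matrices and coarse
("impaired vs intact") accuracies after merging label groups; merging
can only preserve or improve accuracy, which the tests check
exhaustively on small cases.

## The synthetic cohort generator

No item-level dataset of this kind is publicly deposited, so the
package generates latent-class cohorts that emulate the statistical
structure such data shows (`profile_bank()`, `simulate_cohort()`,
`simulate_cohort_pair()`).

Each planted subgroup has an item-success profile built from an
item-knowledge model: items carry difficulties on [0, 1], each subgroup
an ability, and the success probability rises steeply (logistic, width
0.02) from an error floor to a 0.97 ceiling as ability passes
difficulty. Design choices, and why:

* **Expected totals** form an evenly spaced ladder — near the
  four-alternative chance total (0.25 × 36 ≈ 9) up to ~33 of 36 for the
  ASC-like bank (5 profiles), and from mid-range (~20) for the TD-like
  bank (4 profiles) — reproducing the near-linear rank-ordered gradient
  the method is meant to expose. Subgroup abilities are calibrated by
  root-finding so the ladder is hit exactly; `separation` scales its
  spread.
* **Blended difficulty**: item difficulty is 10% a shared backbone and
  90% subgroup-specific. Mastery sets are therefore substantially
  non-nested: subgroups differ in *which* items they know, not only in
  how many. This mirrors the empirical observation that item-difficulty
  profiles correlate only weakly between most subgroups, and it is what
  makes the subgroups discoverable: a purely nested gradient makes
  middle subgroups resemble everyone (see limitations below).
* **Systematic errors** (`error_floor = 0.05`): success on clearly
  unmastered items is 0.05, below the 0.25 guessing rate, modelling
  convergence on the same compelling foil rather than independent
  guessing. Independent guessing would force within-subgroup Hamming
  distances of ≥ 0.375 on unmastered items, contradicting the high
  within-subgroup similarity low-performing subgroups show in real
  data; consistent errors make low performers coherent. The guessing
  rate still anchors the lowest subgroup's *expected total* near
  chance.
* **Distinctiveness rejection**: candidate profile sets with minimum
  pairwise root-mean-square difference below 0.36 are redrawn (up to
  50 attempts, deterministic in the seed), so every bank seed yields
  clearly distinct subgroups.
* Optional knobs default to off: per-subject logit-scale ability jitter
  (`ability_jitter = 0`) and timeout injection (`timeout_rate = 0`).

What the generator does *not* emulate: within-class item dependence
beyond the latent class (local independence is assumed), response
times, item content, covariate structure (phenotypes must be supplied
separately), and any particular real dataset's subgroup prevalences
(cohort pairs draw mixing proportions uniformly within ±30% of equal).
Passing the recovery tests therefore shows the pipeline recovers
latent-class structure of this strength at these sample sizes — not
that any particular real cohort contains such structure.

## Numerical and degenerate-input choices

* TOM is validated against symmetry and [0, 1] range; the triple-loop
  oracle agreement tolerance in tests is 10⁻¹², Ward height agreement
  10⁻¹⁰.
* A dissimilarity with all merges at one height short-circuits to a
  single cluster before any criterion is evaluated.
* Zero pooled variance raises an explicit undefined-effect error in
  `cohens_d()`; constant difficulty profiles make a correlation cell
  untestable rather than NA-propagating.
* Single-class training labels return a degenerate constant predictor
  with a warning instead of an error, so permutation loops cannot die
  on an unlucky shuffle.
* In the weighted discriminant, class priors are floored at 10⁻³⁰⁰
  inside the log to avoid −Inf on vanishing class weights.

## Problem sizes used by the tests

The packaged study-scale fixtures are n = 400 (ASC-like, 5 profiles)
and n = 320 (TD-like, 4 profiles) subjects over 36 items, with 20
seeded replicates for recovery and modal-K checks; cohort pairs for
transfer checks use n = 400 discovery / 250 replication. The
permutation-calibration simulation uses a reduced two-class design
(n = 80 training, 60 test, 12 items, 99 permutations, 200 replicates),
and unit tests use small matrices throughout. The end-to-end pipeline
test runs reduced cohorts (120–150 subjects) with `n_perm = 15`.

## Known limitations

* **TOM on dense gradient structure.** With adjacency `1 − d` on binary
  data, the plain unsigned TOM inherits a hub-attraction bias: when one
  group of subjects (or items) is internally incoherent while another
  is coherent and moderately similar to everyone, the incoherent
  elements can overlap more with the "hub" group than with each other.
  This is why the generator's realism choices (coherent low performers,
  non-nested mastery) matter, and why the planted easy/difficult item
  test uses internally coherent difficult items. On data whose lowest
  stratum is pure independent guessing, this pipeline — by
  construction, not by implementation accident — will not isolate that
  stratum cleanly.
* `K` is whatever the tree cut finds; there is no stability selection,
  bootstrap, or model-based choice of `K`, and no fuzzy assignment.
  With perturbed mixing proportions the smallest planted subgroup is
  occasionally absorbed by a neighbor (the cut returns `K − 1`), which
  is visible in the rank alignment of a cohort pair.
* Item-response-theory measurement modelling (2PL/3PL, measurement
  invariance across subgroups) is out of scope; subgroup sizes produced
  at these cohort scales would be too small for it in any case.
* The permutation test refits the ensemble per permutation, which is
  exact for the stated null but costs `n_perm × rounds` discriminant
  fits; use the `n_perm` flag deliberately.
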