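---
title: "Classifying, designing and scanning insect neuropeptides from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying, designing and scanning insect neuropeptides from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropeptidr)
```

## The problem

Insect neuropeptides are short secreted peptides (roughly 5–80 residues)
that regulate feeding, moulting, diuresis and reproduction, which makes
them — and their receptors — attractive leads for species-selective pest
control. Experimentally validated neuropeptides are curated in public
databases, but there is no repository of validated *non*-neuropeptides, so
supervised classification has to manufacture its negative class, and any
procedure that does so must prove that the signal it learns is biological
rather than an artifact of how the negatives were built. This package
implements the full workflow — encoding, benchmark construction, training,
evaluation, and the two downstream engineering tools (single-mutant design
and protein scanning) — with every stochastic step seeded and every
assumption testable on synthetic data.

## Encodings

Four encodings turn a variable-length peptide into a fixed-length vector.
All of them order the 20 residues alphabetically by one-letter code, so any
two runs produce bit-identical columns.

**Amino-acid composition (AAC).** `Comp(i) = 100 * R_i / N` for each
residue `i`; 20 dimensions summing to 100. Composition is order-free: a
peptide and its reversal encode identically.

**Dipeptide composition (DPC).** The percent frequency of each ordered
residue pair among the `N - 1` overlapping length-2 windows; 400 dimensions
summing to 100. We divide by `N - 1` — the number of windows — rather than
by the number of possible dipeptides, which makes the vector a proper
distribution; dividing by a constant 400 would leave the encoding dependent
on peptide length in a way that sums to anything.

**Split (terminus) composition.** AAC or DPC of the first or last
`k ∈ {5, 10, 15}` residues, or of the joined NkCk segment. The joined
composition is the composition of the concatenated 2k-mer, not two stacked
per-terminus vectors. When `k ≤ L < 2k` the two windows overlap in the
middle and the joined segment still has 2k residues; peptides shorter than
`k` are excluded from that encoding by the dataset-level encoder, with a
warning, rather than silently padded.

**Binary profiles.** One-hot encoding of a terminus window: 20 bits per
position, `A = (1, 0, …, 0)` through `Y = (0, …, 0, 1)`, blocks
concatenated N-to-C (so N10C10 has 400 bits, exactly 20 of them set).
Unlike the compositions, this preserves residue order and absolute
position, which is what makes it effective when positives and negatives
have similar overall composition.

## Benchmarks

`benchmark_dataset()` holds positives and negatives disjoint by sequence.
Both classes pass through exact-identity deduplication only — two sequences
differing in a single residue are both kept, because single substitutions
can change a peptide's activity, and that is precisely the granularity the
design tool needs to rank.

**Random negatives** (`sample_random_negatives()`) are contiguous fragments
of background proteins. Two choices here are ours and matter:

1. *Length matching.* Fragment lengths are drawn from the multiset of
   positive lengths (the length is drawn first, then a protein long enough
   is picked), so the negative length distribution equals the positive one
   exactly and length cannot act as a trivial discriminative leak. DPC
   otherwise betrays length through its quantisation: a 6-mer's entries are
   multiples of 20, an 80-mer's of ~1.27.
2. *One fragment per protein* (`max_per_protein = 1`, used by the
   generator). Overlapping fragments of one protein are near-duplicates;
   when they land in different cross-validation folds the classifier
   "recognises" test negatives from training and specificity inflates above
   chance. With one fragment per protein the zero-signal benchmark is
   exactly exchangeable between classes.

**Hard negatives** (`build_similar_negatives()`) make the task deliberately
difficult: for each positive in input order, the unused candidate with the
smallest Euclidean distance between AAC vectors is taken (greedy, without
replacement, ties to the lexicographically smallest id). Greedy matching is
simpler and more transparent than a globally optimal assignment, and the
property that matters — a strictly smaller mean positive-to-negative
composition distance than random matching — holds either way and is
asserted in the tests.

**Splits and folds.** The 80/20 train/validation split and the five folds
are stratified by class, with `floor(fraction * n)` per class in training.
Stratification is our choice (a plain random split would drift on
imbalanced data); the floor convention reproduces familiar arithmetic such
as 875 per class → 700 train / 175 validation, and 700 + 700 training →
five folds of 140 + 140.

## Learners and model selection

`npp_train()` is the core fitting function; it returns an `npp_model` whose
`predict()` method emits one finite score per peptide, oriented so higher
means more neuropeptide-like. Scores are signed margins for the SVM
learners and probability-of-positive minus 0.5 for the probabilistic
learners, so 0 is a sensible default threshold everywhere. The SVM cost
factor `j ≥ 1` multiplies the misclassification cost of positives: on
imbalanced data, raising `j` never decreases training sensitivity (a
contract the tests check over `j = 1..5`).

The learners themselves are the standard implementations (e1071 SVMs,
randomForest, rpart, e1071 naive Bayes) behind a uniform interface; the
sequential-minimal-optimisation learner of some toolkits is represented by
a linear-kernel margin classifier. Gaussian naive Bayes degenerates on
features with zero within-class variance — common for sparse DPC columns —
so such columns are dropped before fitting and the kept set is stored with
the model. Tree defaults are `c = 0.01` (complexity/pruning) with minimum
leaf size 7; the forest default is 70 trees.

`grid_search()` evaluates every hyperparameter combination by stratified
five-fold cross-validation and selects the highest mean CV accuracy, ties
broken by higher mean MCC, then by smaller `c`. The full default SVM
grid is `g ∈ {1e-4 … 10}` (log-spaced), `c ∈ 1..15`, `j ∈ 1..5`; the
examples and the acceptance script use a 6-point subset
(`g ∈ {1e-3, 1e-2, 5e-2}`, `c ∈ {1, 5}`, `j = 1`) that keeps a full run
under a minute at 500 peptides per class without changing any conclusion.

## Evaluation

Threshold-dependent measures (sensitivity, specificity, accuracy in
percent, and MCC) derive from confusion counts with "score ≥ threshold"
predicting positive. MCC returns 0 when any factor of its denominator is
zero — the standard convention for degenerate tables. AUROC is the rank
statistic with ties counted half, which equals the trapezoidal area under
the TPR-vs-FPR curve; the tests verify it against exhaustive pair counting
on every small toy and against an independent ROC implementation.

`threshold_sweep()` tabulates performance at every distinct score and
exports a default threshold: the accuracy-maximising cut, ties broken by
the smallest |sensitivity − specificity| and then by the median remaining
candidate, placed midway between the winning score and the next-lower
distinct score. The midpoint matters: a threshold sitting exactly on an
observed training score misclassifies held-out peptides that land just
below it, which both depressed a separable toy below 100% and cost about a
point of CV accuracy on realistic benchmarks before we moved the cut to the
gap's midpoint.

`cross_validate()` trains on four folds, picks the fold's threshold from
its *training* scores (never from the held-out fold, which would bias the
null upward), and evaluates the held-out fold; headline numbers are
unweighted means over folds, with a pooled-score report for diagnostics.

## Analysis, design, scan

`mean_composition()` weights peptides equally regardless of length;
`positional_composition()` tabulates the residue distribution at the first
five positions from either terminus (C-terminal position 1 is the last
residue). `find_exclusive_motifs()` is an exact substring miner: every
3–6-mer present in at least `min_support` positives and in zero negatives,
support counted as peptides-containing rather than total occurrences, with
sub-motifs suppressed when a longer returned motif has identical support.
It deliberately replaces degenerate-alphabet motif tools with a transparent
primitive: what it finds is exactly recountable, at the price of missing
gapped or physicochemically generalised patterns.

`single_mutants()` enumerates all `19L` single-point substitutions (the
identity substitution is excluded); `rank_mutants()` scores them plus the
original and sorts by score, supporting iterative redesign.
`scan_protein()` scores all `L − w + 1` overlapping windows with 1-based
inclusive coordinates; the default window of 15 sits mid-range of the
terminus window sizes the encodings use, and is user-selectable.

## The synthetic generator, and what passing tests do not show

`generate_signal_peptides()` plants three kinds of structure, all scaled by
a single `effect_size`: enrichment of a favored residue set (default C, D,
E, F, G, N, S, Y at enrichment factor 3, i.e. weight `3^effect_size`),
per-position terminal preferences (defaults N, F, D, S, I at N-terminal
positions 1–5 and L, F, N, G, L at C-terminal positions 1–5, each imposed
with probability `0.5 · min(effect_size, 1)`), and optional motifs inserted
in place with a stated probability. An amidated variant
(`signal_spec_amidated()`) carries the C-terminal amide flag and its own
preference defaults (A/P/S at the N-terminus, L/R/P/F at the C-terminus).
At `effect_size = 0` every bias vanishes and positives are exchangeable
with the uniform background — the null-calibration tests depend on this.
Lengths are uniform on 5–80, the range the positive class occupies.

The defaults are chosen once to mirror the compositional and positional
findings reported for natural insect neuropeptides; `effect_size = 2` is
used as the "strong signal" condition in the end-to-end tests (favored
residues then carry ~86% of the probability mass, a caricature of the real
enrichment that makes the discriminability ceiling unambiguous), and
`effect_size = 1` elsewhere.

What the generator does *not* emulate: real neuropeptide families share
evolutionary homology (near-identical paralogues), prepropeptide cleavage
context, and correlated residue usage beyond first-order composition.
Passing the strong-signal test therefore shows the pipeline can recover a
planted compositional/positional signal at realistic sample sizes — it does
not certify the accuracy the method reaches on curated neuropeptide data,
which additionally depends on homology structure the generator omits.

## Sizes, seeds and numerical choices

The end-to-end tests and the acceptance script run at 500 peptides per
class (800 training / 200 validation after the 80/20 split), five folds,
DPC features, and the 6-point SVM grid — about half a minute on one CPU.
Every random step (generation, negative sampling, splitting, folding,
stochastic learners) takes an explicit integer seed and restores the
caller's RNG state; the same seed reproduces a benchmark byte-for-byte.
Feature matrices carry their scheme name, and models refuse prediction
under a mismatched scheme. Composition sums are exact to 1e-9; metric
identities are tested to 1e-12; two-decimal report comparisons use
|Δ| ≤ 0.005.

## Known limitations

- Negative classes are assumed, not validated: a "background" fragment may
  in truth be bioactive. The construction makes this unlikely, not
  impossible.
- Exact-identity deduplication leaves homologous near-duplicates in the
  data, so cross-validation estimates are optimistic for deeply redundant
  positive sets; homology-aware splitting is out of scope.
- The motif miner is exact-substring only.
- Hyperparameter semantics of the classical SVM and decision-tree
  toolchains are honoured at the contract level, not reproduced
  bit-for-bit.
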