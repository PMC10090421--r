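---
title: "Classifying anticancer peptides from sequence descriptors: models and conventions"
author: "acpGBDT maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer peptides from sequence descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpGBDT)
```

## The problem and the model

Anticancer peptides (ACPs) are short, mostly cationic peptides that lyse or
otherwise selectively kill tumor cells. Given a peptide's primary sequence,
`acpGBDT` predicts whether it is an ACP. The pipeline is: encode each
sequence into a fixed-length numeric descriptor, merge two complementary
descriptor families into one feature matrix, train a gradient boosted
decision tree (GBDT) on labeled examples, and report
sensitivity/specificity/accuracy/MCC/AUC under stratified ten-fold
cross-validation or an independent test.

GBDT fits an additive ensemble of shallow regression trees, each tree fitted
to the residual of the current ensemble under the logistic loss. Trees are
scale-invariant, handle correlated blocks of features gracefully, and need
no feature standardization — well matched to a descriptor that mixes
frequencies in [0, 1] with raw physicochemical indices spanning orders of
magnitude.

## The 188D descriptor

`encode188()` produces 20 + 8 × 21 = 188 values:

* **Composition (20).** `v_i = N_i / L` in alphabetical residue order;
  the entries sum to 1 for any non-empty sequence.
* **CTD blocks (8 × 21).** Each of eight physicochemical properties
  partitions the 20 amino acids into three ordered groups
  (`ctdGroupings()`). Per property: 3 group frequencies; 3 transition
  frequencies (adjacent residue pairs crossing groups 1↔2, 1↔3, 2↔3,
  both directions, divided by the number of adjacent pairs `L − 1`); and
  15 distribution values — for each group, the 1-based positions of its
  first occurrence, its `⌈n·q⌉`-th occurrence for q = 25%, 50%, 75%
  (n = occurrences of that group), and its last occurrence, each divided
  by `L`.

Conventions we had to fix because the descriptor family leaves them open:

* **Percentile convention.** "25% occurrence" is the `max(1, ⌈n·q⌉)`-th
  occurrence of the *group*, not a fraction of the sequence length. This is
  the occurrence-count convention of the canonical CTD "distribution"
  descriptor; it guarantees the five values per group are monotonically
  non-decreasing and lie in (0, 1].
* **Empty groups** contribute five zeros, keeping the vector length and
  bounds fixed.
* **Length-1 sequences** have no adjacent pairs; transitions are 0, not an
  error.
* **Group tables.** The three-group partitions are the canonical
  Dubchak-style tables used by SVM-Prot-family encoders, shipped as code
  and serializable to a plain-text config (`writeGroupings()` /
  `readGroupings()`) so they are auditable and swappable. The property
  order and within-block order (3 composition, 3 transition, 15
  distribution) are frozen: they define feature-column identity, and the
  layout fingerprint travels with every `FeatureMatrix` and trained model.

## The AAindex descriptor

AAindex1 assigns each amino acid one value per physicochemical index.
`encodeAAIndex()` requires equal-length input, so sequences are reduced to
their **first ten plus last ten residues** (`truncate20()`); termini carry
much of an ACP's membrane-interaction signal, and this keeps the encoding
invariant to everything in between. Open corners we decided and flagged:

* For `10 ≤ L < 20` the literal first-10 + last-10 rule duplicates the
  overlap — applied as stated.
* For `L < 10` the result is right-padded with a pad symbol whose property
  values are all 0; pad positions are flagged in `padMask`. Padding rather
  than erroring keeps very short peptides encodable; the mask records that
  the zeros are synthetic.
* Values are used raw, as distributed. The layout is position-major
  (`20 × P`): all `P` properties of position 1, then position 2, and so on.
* The full database is taken from seqinr's bundled AAindex1 copy
  (`aaindexFull()`): 544 indices, of which the 13 containing missing
  values are dropped, leaving 531 complete properties — so the full merged
  descriptor has 188 + 20 × 531 = 10,808 columns. Unit-scale work uses the
  bundled 6-index TSV fixture (`aaindexMini()`, 308 merged columns).

## Model and evaluation conventions

* **Hyperparameters.** `modelConfig()` defaults to 100 trees, learning rate
  0.1, depth 3, seed 42 — the common library defaults for gradient
  boosting. The boosting implementation is xgboost with the L2 penalty
  disabled and exact greedy splits, i.e. plain gradient boosting; the
  `xgboost` classifier kind keeps the library's own regularization
  defaults. Comparison kinds (random forest, decision tree, kNN, logistic
  regression, Gaussian naive Bayes) delegate to the standard R
  implementations; AdaBoost is a minimal SAMME booster over depth-1 rpart
  stumps. Distance- and margin-based classifiers can opt into
  standardization, fitted on training folds only to avoid leakage; tree
  models use raw features.
* **Decision threshold** is fixed at 0.5, with exact ties called positive.
  Classes are balanced by design in this protocol, so 0.5 is the natural
  operating point.
* **Cross-validation** is stratified: within each class, shuffled records
  are dealt round-robin into k folds, so a 250/250 set yields ten 25+25
  held-out folds. Both encoders are stateless (no fitted parameters), so
  the dataset is encoded once before splitting without leakage. Metrics
  are computed once on the pooled out-of-fold predictions — stable for MCC
  and AUC at n = 500 — and per-fold metrics are retained so fold-averaged
  summaries can also be inspected; pooled ACC equals the count-weighted
  mean of fold ACC by construction. The fold seed is independent of the
  model seed.
* **Undefined metrics** (a zero confusion-table marginal) are reported as
  `NaN` with a warning, never silently 0. MCC marginal products are
  computed in double precision: at n = 500 they overflow 32-bit integers.
* **AUC** is the midrank Mann–Whitney statistic (ties count half), which
  equals trapezoidal ROC integration on tie-free scores.
* **Reports** print percentages with one decimal (90.4, not 0.904), columns
  SE, SP, ACC, MCC, AUC; internal values stay proportions.

## What the synthetic generator emulates — and what it does not

`generateFixture()` emits uniform-length (10–50) random peptides; with a
`bias` such as `c(K = 3, R = 3)` the positive class samples the named
residues with multiplied weight, mimicking the cationic enrichment of real
ACPs. That makes the classes separable through composition features, so the
full pipeline can be exercised offline: at n = 500 with that bias the
merged-feature GBDT reaches cross-validated accuracy in the mid-80s, and
with permuted labels it sits at chance.

The generator does **not** emulate residue-order structure (amphipathic
periodicity, motifs), length–class associations, homology clusters, or
database composition quirks. Passing tests therefore demonstrate that the
machinery is correct and calibrated — not that any particular accuracy will
transfer to curated ACP benchmarks. Reproducing published-benchmark numbers
requires the curated 250/250 training and 82/82 test FASTA files and the
full AAindex release, loaded with `readPeptideFasta()` one file per class
(a sidecar id–label TSV is the secondary dialect via `applyLabels()`).

## Problem sizes used in the checks

The shipped checks run at the protocol's native scale where that is cheap:
1,000 random peptides for encoder structure and normalization; 1,000 random
instances per oracle-equivalence check (CTD, confusion metrics) plus 100
tie-free score sets for AUC; 50 permutation seeds × ten-fold CV at
n = 500 on the 188D block for null calibration; and one ten-fold CV at
n = 500 on the merged 308-column fixture encoding for signal recovery. The
6-index AAindex fixture stands in for the 531-index database in the
signal-recovery run; the composition signal the generator plants is fully
visible to it.

## Known limitations

* The AAindex truncation discards interior residues of long peptides by
  design; descriptors sensitive to mid-sequence motifs need a different
  encoder (the encoder interface accepts any object with `name`, `dim`,
  `layout` and `encode` fields).
* No feature selection is performed; the 10,808-column full encoding is
  handed to the tree ensemble as-is.
* kNN tie probabilities come from neighbor voting with k = 5; with even k
  the vote can tie and the backend's tie-breaking applies.
* `aaindexFull()` reflects the AAindex release bundled with seqinr; a
  different release may retain a different property count, which the layout
  fingerprint will surface as a mismatch rather than silently mixing
  encodings.

## Session info

```{r}
sessionInfo()
```
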