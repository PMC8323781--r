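---
title: "Classifying protein families with reduced amino acid alphabets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein families with reduced amino acid alphabets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raacpred)
```

## The problem

Many protein families — the 2-oxoglutarate/Fe(II)-dependent oxygenases are
the motivating example — are defined less by overall sequence similarity
than by the physicochemical character of a conserved catalytic core: a
2-His-1-carboxylate iron-binding triad (an `H-x-D ... H` pattern) embedded
in a broadly polar active-site region. raacpred implements a binary
sequence classifier built around that observation: instead of the full
20-letter alphabet, sequences are first rewritten over a *reduced amino
acid cluster* (RAAC) alphabet that merges physicochemically similar
residues, and the classifier works on k-mer compositions of the reduced
sequence.

The pipeline is:

1. **Reduce**: map each residue to the representative of its group under a
   reduction scheme with $s$ groups ($2 \le s \le 19$).
2. **Encode**: count the $L - k + 1$ overlapping k-mers ($k \in \{1,2,3\}$)
   of the reduced sequence and normalise to frequencies
   $d_i = n_i / \sum_i n_i$, giving an $s^k$-dimensional composition vector.
3. **Rank**: score each feature by the one-way two-group ANOVA F statistic
   (between-class mean square over pooled within-class mean square).
4. **Select**: incremental feature selection (IFS) — walk nested prefixes
   of the ranking, score each by cross-validated accuracy, keep the
   smallest prefix attaining the maximum.
5. **Classify**: an RBF-kernel SVM, hyperparameters chosen by exhaustive
   grid search over $2^{-5} < C < 2^{15}$, $2^{-15} < \gamma < 2^3$
   (exponent step 2), evaluated by stratified 10-fold cross-validation
   with the full metric set (Sn, Sp, F1, Acc, MCC, ROC/AUC).

## Reduction schemes

A scheme is a partition of the 20 canonical amino acids into ordered
groups, written `"S-T-A-N-D-G-RQ-EK-H-P-IV-L-M-WYF-C"`. The package ships
the 18 nested schemes of the substitution-matrix-derived family indexed as
type 33 (sizes 2–19), whose coarsest split separates polar from
hydrophobic residues; `read_scheme_library()` loads further user-supplied
catalogues. The representative letter of a group is its first listed
letter: the printed notation fixes no convention, and first-letter
representatives make reduction deterministic and readable.

Non-canonical letters (B, J, O, U, X, Z, `*`) occur in real databases but
carry no composition information here; the default policy drops them with
a per-sequence count (`"error"` aborts instead). This is a package
decision — curated corpora rarely document their own handling of
ambiguity codes.

## Feature encoding choices

* The composition denominator is the overlapping-window count $L - k + 1$,
  so every row sums to exactly 1; this is the natural reading of
  $d_i = n_i/\sum n_i$ and makes rows comparable across lengths.
* Feature order is lexicographic over group indices, most significant
  first — stable across runs and platforms.
* $k$ is capped at 3 ($s^k$ reaches 6859 at $s=19$); larger $k$ is
  rejected loudly rather than silently accepted.
* One model uses one $(s, k)$ encoding. A multi-encoding concatenation is
  deliberately not the default: the scan (`scan_schemes()`) exists to pick
  the best single cell.

## Feature ranking and IFS

For two groups the ANOVA F statistic reduces to the squared two-sample
t statistic; we compute it directly as
$F = \mathrm{MS}_{between}/\mathrm{MS}_{within}$ with 1 and $n-2$ degrees
of freedom. Degenerate cases are explicit: a feature constant everywhere
scores 0; a feature with zero within-class variance but distinct class
means has infinite F and is capped just above the largest finite score, so
it ranks first while keeping all scores finite. Ties in the ranking break
by ascending feature index, for determinism.

IFS evaluates nested prefixes at dimensions `step, 2*step, ...`. The
default `step = 1` is exhaustive; the package's own large runs use
`step = 25` on 225-dimensional encodings, which resolves the accuracy
curve finely enough while keeping a desk-scale run in minutes.
Hyperparameters inside IFS follow `tune = "once"`: one grid search at the
full candidate dimension, then fixed along the curve ("per_dim" re-tunes
at every prefix; "none" uses supplied values).

## SVM and cross-validation

The SVM engine is libsvm via e1071 — the standard choice, and the same
engine family the RAAC literature uses. Composition features are already
bounded in $[0,1]$ and are passed to the kernel unscaled. Class weighting
is off by default (the intended training sets are balanced).

Two fold layouts are used, both stratified and seeded:

* **Grid screening** uses 5-fold CV (`grid_folds`), the default of
  libsvm's own grid-search tool; ties on accuracy break to smaller $C$,
  then smaller $\gamma$, favouring the least complex model.
* **Evaluation** uses 10-fold CV (`folds`), pooling out-of-fold
  predictions for the reported metrics; per-fold accuracies are also
  returned. Pooled reporting is the package default because it yields one
  well-defined confusion matrix.

Fold assignment deals each class round-robin after a seeded shuffle, so a
fixed seed gives bit-identical folds, grids, chosen hyperparameters and
reports. Probability estimates use libsvm's sigmoid coupling with a fixed
internal seed; because that calibration can be flat on weak models, the
predicted label is always taken from the sign of the decision value, never
from the probability.

## Evaluation metrics

Sn, Sp, F1, Acc and MCC follow their confusion-matrix definitions; any
metric with a zero denominator is reported as `NA` with an explanatory
note rather than silently coerced to 0 — a degenerate classifier should
look degenerate. AUC is the Mann–Whitney rank statistic with half-credit
for ties, which equals the trapezoidal area under the threshold-swept ROC
curve; the test suite asserts that equality to $10^{-12}$.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure the classifier
exploits, so the whole pipeline can be exercised and tested with no
external corpus:

* **Positives** carry exactly one motif instance — default segments
  `c("HxD", "H")` with a background spacer of uniform length 10–40 —
  written at a uniformly random feasible position, with per-literal
  substitution noise (`motif_noise`, default 0.1), on a background tilted
  toward the 12 polar residues by `positive_bias` (default 0.25, mixing a
  uniform-polar distribution into the background).
* **Negatives** are pure background (default uniform 1/20 per residue;
  uniform keeps background motif-match rates in closed form, which the
  tests verify by counting matches over 10,000 sequences).
* Default sizes are 240 sequences per class of length 120–300, the scale
  of a curated, redundancy-filtered two-class family benchmark.

What the generator does **not** emulate: phylogenetic correlation between
sequences, domain architecture, length/composition confounds, or database
ambiguity codes. Passing tests on synthetic data therefore demonstrate
that the machinery is correct and that the pipeline detects the kind of
signal it targets — not that any particular accuracy will transfer to a
real corpus.

`identity_filter()` is a deliberately simple greedy redundancy filter
(ungapped identity over the shorter length, first-seen representative
kept). It approximates what clustering tools such as CD-HIT do during
benchmark construction and is labelled an approximation; it is not a
reimplementation of any such tool.

## Null behaviour and post-selection optimism

On label-permuted data, a grid-searched SVM evaluated by pooled 10-fold CV
sits at chance (within binomial noise): the grid screening and the
evaluation use different fold layouts, so the reported accuracy is not the
maximised screening statistic.

Running the *full* chain — ANOVA ranking and IFS on the complete data,
then CV on the same data — on permuted labels does **not** sit at chance:
feature selection performed outside cross-validation sees every test fold
and is optimistically biased (at 480 samples × 225 features it reaches
accuracies near 0.6 on pure noise). This is a property of post-selection
CV estimates, not of the implementation; the package's null checks
therefore omit data-dependent selection, and users should treat the
post-IFS CV accuracy as an upper estimate unless selection is nested
inside an outer validation split.

## Problem sizes used in tests and reproduction runs

The shipped checks run the full default conditions (240/class, $s=15$,
$k=2$, IFS step 25, full grid) once for the signal arm and once for the
permutation null; module tests use smaller draws (tens of sequences,
reduced grids) chosen to keep each property sharp at small n. All sizes
are stated in the tests themselves.

## Known limitations

* The greedy identity filter is order-dependent and alignment-free.
* IFS explores only nested prefixes of one ranking; interactions between
  features outside that order are invisible to it.
* MCC/metric undefined states are reported but not imputed; downstream
  code must handle `NA`.
* Linear/polynomial/sigmoid kernels are reachable through e1071 but are
  not tuned paths in this package.
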