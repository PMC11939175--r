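---
title: "Weight-based feature selection and majority-voting ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-based feature selection and majority-voting ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwinca)
```

## The problem

Screening text for signs of depression or suicidal ideation is typically cast
as supervised classification over sentence embeddings: each document becomes a
dense numeric vector (often several such vectors, one per pre-trained language
model), and a conventional classifier is trained on the labels. Two practical
obstacles dominate. First, concatenated embeddings are high-dimensional and
highly redundant, which hurts both accuracy and interpretability; second, no
single embedding/classifier combination wins consistently across platforms and
datasets. This package implements a complete, reproducible treatment of both:
per-feature NCA weighting with cumulative-weight iterative subset selection
(CWINCA), and iterative hybrid majority voting (IHMV) over the out-of-fold
prediction vectors of a classifier bank.

Everything runs on plain data frames (feature columns plus one label column)
and is exercised end-to-end by synthetic generators, so no external corpora or
model downloads are required.

## NCA feature weighting

`nca_fit()` learns one nonnegative weight per feature by maximizing the
regularized expected leave-one-out 1-NN accuracy. With weighted L1 distances

$$d_w(i,j) = \sum_r w_r^2\,|x_{ir} - x_{jr}|,$$

reference probabilities are a softmax over negative distances,
$p_{ij} = \exp(-d_w(i,j)) / \sum_{k \ne i} \exp(-d_w(i,k))$ with
$p_{ii} = 0$, each sample's score is the probability mass on same-class
neighbors, $p_i = \sum_{j:\,y_j = y_i} p_{ij}$, and the objective is

$$F(w) = \frac{1}{n}\sum_i p_i \;-\; \lambda \sum_r w_r^2 .$$

Weights enter only through $w_r^2$, so the sign is meaningless; fitted models
store the nonnegative representative. The softmax is evaluated with
max-subtraction, which changes nothing semantically but cannot overflow.

Tunable parameters (all unitless):

* `lambda` — L2 penalty; default `1/n`, which keeps weights bounded without
  overwhelming the data term at typical sample sizes.
* `learning_rate` — base SGD step, default 0.01, decaying as
  $1/\sqrt{\text{epoch}}$.
* `epochs` — maximum passes, default 50; an early stop fires when the relative
  epoch-end objective change stays below `tolerance` (default 1e-6) for three
  consecutive epochs.
* `seed` — fully determines the per-epoch visit order, making fits
  bit-reproducible.

The solver is plain per-sample stochastic gradient ascent from an all-ones
start. One numerical caveat matters in practice and is worth stating plainly:
on raw, unscaled features the pairwise distances can be large enough that the
softmax saturates (each row's probability mass collapses onto a single
neighbor), gradients vanish, and the fit stalls wherever it started. This is
precisely why the selection procedure min-max normalizes features *before*
fitting; `nca_fit()` on its own should be given data on a roughly unit scale.

## CWINCA subset selection

`cwinca_select()` wraps the weights in a deterministic search:

1. **Normalize.** Each column is mapped to
   $(x - \min)/(\max - \min + \epsilon)$, so outputs lie in $[0, 1)$;
   `epsilon` (default 1e-8) exists to make constant columns map to zeros
   rather than 0/0.
2. **Rank.** Features are sorted by descending weight; ties break by
   ascending original position so runs are reproducible.
3. **Bound the sweep.** With the normalized cumulative weight curve, the
   start size is the smallest rank reaching 0.5 and the stop size the
   smallest rank reaching 0.999. If the curve never reaches a threshold
   (all-zero weights), the start falls back to 10 — clamped to $d$ for
   narrow matrices — and the stop to $d$.
4. **Evaluate.** For every size $s$ in `[start, stop]`, the top-$s$ ranked
   features are scored by 10-fold cross-validated 1-nearest-neighbor
   misclassification (cityblock distance, per-fold standardization computed
   on the training folds only).
5. **Choose.** The chosen size is the *first* minimal loss — the smallest
   subset on ties, which prefers parsimony.

Candidate subsets are nested by construction (each size adds one ranked
feature), so the search is linear, not combinatorial. The same seeded,
class-stratified fold assignment is reused for every candidate size: fold
noise then cancels in the size comparison, and the whole trace is
reproducible from one seed. Stratification falls back to plain seeded k-fold
(with a warning) when a class has fewer members than folds.

One statistical subtlety is deliberate: by default, selection sees the full
dataset and classifiers are cross-validated afterwards on the selected
columns. That mirrors the procedure this package models, but it leaks label
information into the feature choice, so the out-of-fold accuracies are mildly
optimistic. `run_pipeline(nested = TRUE)` instead re-runs selection inside
every training fold (normalizing held-out rows with the training fold's
min-max map), which is the leakage-safe estimate; it costs one full selection
per fold. Selected columns are passed forward on the normalized scale without
re-normalization.

## Classifier bank and prediction vectors

`crossval_predictions()` produces, for one classifier, the out-of-fold
prediction vector: every sample predicted by a model trained on the folds
that exclude it. Out-of-fold (rather than refit-on-all) vectors are used
because only they carry honest accuracies for ensemble ranking. The bank
mirrors the standard families — polynomial-kernel SVM (degree 3, C = 1,
features already normalized upstream), 1-NN with cityblock distance and
per-fold standardization (the same engine the selection loop uses, so the
two agree exactly on shared folds), a CART tree, a one-hidden-layer network
(100 units), L2-penalized multinomial logistic regression, and bagged trees
(30 learners, all features per split). Families and defaults are pinned in
`classifier_spec()` and overridable; every stochastic fit is seeded per fold.

## Iterative hybrid majority voting

`ihmv()` sorts the prediction vectors by accuracy, applies mode voting to the
top-$k$ for every $k$ from 3 to $m$ (a bank smaller than 3 votes all its
members), and keeps the voted labeling with maximal accuracy, preferring the
smallest $k$ on ties. Starting at $k = 3$ avoids degenerate one- and
two-model "ensembles"; evaluating $k = m$ guarantees the result is never
worse than the plain all-model vote. The "hybrid" weighting of better models
is realized through the accuracy-based ranking and depth selection, not
through fractional vote weights: within each ensemble every model casts one
vote. Vote ties resolve to the choice of the best-ranked model among those
voting for a tied label, then to the smallest label in canonical order —
deterministic, and using the only ranking signal available.

Choosing $k$ requires truth labels, so `ihmv()` is a calibration-time
procedure. At deployment, freeze the calibrated $k$ and apply `mode_vote()`
to the accuracy-ranked top-$k$ columns.

## Metrics

`compute_metrics()` reports the confusion matrix (rows = truth), accuracy,
and per-class precision, recall, and F1 as percentages, with macro averages
as unweighted class means. A class never predicted has undefined precision;
it is reported as 0 with a warning rather than dropped, which keeps macro
averages honest on degenerate predictions.

## Text frontend

`clean_text()` lowercases, strips punctuation and symbols, collapses runs of
three or more repeated characters to two ("soooo" → "soo"), tokenizes on
whitespace, and removes stopwords from a pinned list shipped with the
package; the function is idempotent. Spelling correction is a deliberate
no-op: no dictionary or method is pinned anywhere authoritative, and a silent
aggressive corrector would be untestable.

`embed_texts()` turns a corpus into a feature matrix. The deterministic
hashing backend maps each token to a coordinate (hash modulo width) and a
sign, embedding a text as signed token counts — the classic hashing trick.
It is not a semantic embedding: it preserves lexical overlap structure, which
is exactly what the selection and voting stages need for testing, and nothing
more. Transformer adapters (mean pooling over the final layer) are declared
as an interface; since no model weights ship with the package, they error
with instructions to use the hashing backend. Hash widths should comfortably
exceed the distinct-token count — with ~80 tokens, width 64 collides
noticeably while width 128 is nearly collision-free.

## Synthetic generators: what they do and do not show

`make_planted_features()` draws informative columns from class-conditional
Gaussians with unit within-class standard deviation and means `class_sep`
apart, plus independent standard-Gaussian noise columns, with balanced
classes. The defaults (n = 200, 3 informative + 17 noise, separation 2.0)
define the recovery regime the tests use throughout. `make_prediction_ensemble()`
plants per-model accuracies with errors independent across models — the
Condorcet regime in which majority voting provably helps; correlated errors,
which shrink that gain, are exactly what the generator does *not* emulate.
`make_text_corpus()` gives each class a token pool with a controllable shared
fraction; texts are 5–20 tokens long.

Passing tests on these fixtures demonstrates that the machinery does what it
claims under its own assumptions (Gaussian class structure, independent
model errors, lexically separable classes). It does not demonstrate
performance on real social-media text, where embeddings are anisotropic,
classifier errors correlate, and class imbalance is severe.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problems chosen once: planted
fixtures at n = 200 with 20 features across 10 generator seeds; oracle
comparisons at n ≤ 60, d ≤ 12 against loop-based brute-force
re-implementations; voting properties over 100 random ensembles and 100
Condorcet trials at n = 1000; and an end-to-end corpus of 120 texts embedded
at widths 32/64/128 with three classifiers (polynomial SVM, 1-NN, CART),
giving 12 prediction vectors across the three per-backend sets plus their
concatenation. Distance ties in the 1-NN resolve to the earliest training
row; loss ties in the size sweep to the smallest size; vote ties as above —
every tie-break is deterministic, which is what makes byte-identical reruns
possible. All randomness flows from user-supplied integer seeds through
seeded generators; nothing reads the global RNG state.

## Known limitations

* The SGD solver is first-order with a fixed decay schedule; on poorly scaled
  inputs it stalls (see above) and it converges slowly near the optimum.
  Normalize first.
* Default-order selection (select, then cross-validate) inherits the
  selection bias discussed above; use `nested = TRUE` for unbiased estimates.
* IHMV needs labeled calibration data to choose the ensemble depth.
* The hashing backend is a lexical, not semantic, embedder; transformer
  adapters require model weights the package does not ship.
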