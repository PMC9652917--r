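---
title: "Topological texture features for Gleason grading: methods and design"
author: "PHGleason authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological texture features for Gleason grading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PHGleason)
```

# The model

`PHGleason` grades gland images by the persistence of their intensity
topology. The pipeline has four stages, each a module of the package:

1. **Cubical complex** (`cubicalComplex`): the image becomes a filtered
   cell complex under the V-construction — pixels are vertices valued by
   their intensity, edges join horizontal/vertical neighbours and carry
   the maximum of their endpoints, unit squares carry the maximum of
   their four edges. With the max rule, the cells with value at most `a`
   always form a subcomplex, so sorting cells by
   (value, dimension, anchor) yields a filtration equivalent to the
   sublevel sets of the image.
2. **Persistence** (`computePersistence`): column reduction of the Z2
   boundary matrix in filtration order (compiled core) pairs creator and
   destroyer cells into dimension-0 and dimension-1 bars. Essential
   classes — alive at the top of the filtration — receive the finite
   death `m = max(F) + 1` and are flagged.
3. **Window features** (`windowFeatures`, `slideWindows`): overlapping
   square windows (default 50 px; 40 and 60 are conventional
   alternatives and behave similarly) are each summarised by 8 numbers:
   mean/sd of bar lifetimes per dimension, persistent entropy per
   dimension, mean/sd of pixel values.
4. **Classification** (`fitClassifier`, `kfoldEvaluate`): five standard
   learners on window descriptors; gland labels by majority vote over
   windows; repeated stratified k-fold CV with confusion matrices and
   one-vs-rest ROC/AUC.

## Assumptions

* Images are single-channel with meaningful ordinal intensities; raw
  values are used without normalisation, so integer inputs give integer
  filtration levels. Classification is invariant to global intensity
  shifts because six of the eight features are (the two pixel statistics
  are the exception and carry the photometric signal deliberately).
* Connectivity is 4-neighbour; diagonal pixels are not adjacent. This is
  the standard V-construction reading of "horizontal and vertical
  neighbours"; diagonal (8-) connectivity would require the T-construction
  and changes which loops exist at a level.
* Only dimensions 0 and 1 are informative for 2-D images (dimension-2
  homology of a planar complex is trivial, which is also why
  `betti1 = betti0 - chi` holds and powers the test oracle).

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `windowSize` | 50 | px | texture scale of gland architecture; 40/60 give similar results |
| `stride` | `windowSize/2` | px | the common 50% overlap; dataset-scale runs here use stride = window (disjoint 16 windows per 200-px gland) |
| `minCoverage` | 0.5 | fraction | windows mostly outside a gland mask carry background, not architecture |
| entropy `base` | `e` | — | any base rescales all entropies uniformly; nats are conventional |
| `k` | 2–5 | folds | the grading protocol's range |
| `repeats` | 100 | — | the protocol's repetition count; desk-scale runs use 5–10 (see below) |

Classifier hyperparameters are library defaults (`rpart`,
`randomForest`, `e1071::svm` radial, `e1071::naiveBayes`, `MASS::lda`),
recorded in every `EvaluationReport`; the SVM is a one-against-all
ensemble of binary machines whose decision values serve as class scores.
No feature scaling is applied by default — trees, naive Bayes and LDA are
unaffected — with an optional `standardize` flag that mainly matters for
SVM margins.

# Numerical and convention choices

* **Tie-breaks in the filtration**: cells with equal value are ordered by
  ascending dimension, then anchor row, column and edge orientation.
  Deterministic, and facet-safe since a facet never exceeds its coface's
  value.
* **Zero-lifetime bars** (creator and destroyer at the same level) are
  retained in the barcode — they are part of the pairing — but excluded
  from lifetime statistics and entropy: they would contribute `0 log 0`
  terms and mean-lifetime dilution with no geometric content.
* **The essential dimension-0 bar** is included in the statistics with
  its substituted death `m = max(F) + 1`. On near-constant windows it
  dominates dimension-0 statistics (a constant window's descriptor is
  exactly `(1, 0, 0, 0, 0, 0, c, 0)`); that sensitivity is intrinsic to
  the substitution rule and documented rather than suppressed.
* **Standard deviations** use the population convention (divide by `n`),
  so a single bar has sd 0 and empty lifetime multisets have mean and
  sd 0 — descriptors are total over all windows.
* **Empty/single-bar entropy is 0**: with one outcome `p = 1`. With `n`
  equal bars entropy attains its maximum `log n`.
* **ROC** sweeps every distinct score as a threshold and integrates by
  trapezoid; tied scores collapse to one operating point, which matches
  rank-based AUC with ties.
* **Majority-vote ties** resolve to the smallest label in sort order —
  deterministic and label-set agnostic.
* **Windows are never padded**; trailing pixels beyond the last full
  window are dropped. Padding would inject artificial boundary topology.
* Degenerate inputs: single-row/column images form a 1-complex (no
  squares) and are supported throughout persistence; windows below
  2 x 2 and empty/non-finite images are rejected with clear errors.

# Cross-validation design

Fold assignment is stratified by class at the **gland** level: all
windows of a gland stay in one fold, so no window of a held-out gland
ever influences training. Splitting at the window level instead lets
nearly identical neighbouring windows of one gland straddle the
train/test boundary and inflates accuracy through intra-gland
correlation; it remains available (`splitLevel = "window"`) only for
literal replication of window-level protocols. Within each class the
fold sizes differ by at most one, and the per-class leftover assignment
rotates across classes so total fold sizes stay balanced (10 glands,
k = 2 gives a 5/5 split).

Reports expose all three accuracy levels rather than privileging one:
window-level (raw predictions), gland-level (majority vote), and
image-level, defined as the mean over images of the per-image fraction
of correctly voted glands — the global accuracy is the mean of per-image
accuracies. Multi-class AUC is the macro average of one-vs-rest AUCs on
window scores. Across the `repeats` repeated random partitions, reported
accuracies and AUCs are means.

# The synthetic data generator

Real graded tissue images (quantitative phase microscopy of prostate
biopsies, whole slides of order 10,000 px decomposed into ~1,000-px
glands, all glands of a slide sharing a grade) are not redistributable,
so `simulateGland`/`simulateDataset` emulate the *structure* that drives
the pipeline, not the optics:

* A bright gland body (intensity 180 of 255) carries a smoothed
  Gaussian random texture field (three box-filter passes, half-width
  5 px). The smoothing scale controls how many nuisance short-lived bars
  the background contributes.
* **Lumens are dark annular rims** (intensity 40, ring width 3 px,
  radius 6–10 px) around interiors left at body intensity. Under the
  sublevel filtration the dark rim enters early and closes a loop that
  only fills when its brighter interior enters: one long-lived
  dimension-1 bar (lifetime ~140 levels) plus a long dimension-0 bar per
  lumen. A filled dark disk would *not* work — it is contractible at
  every level and creates no loop — which is why the rim geometry is the
  generator's central design choice.
* Classes differ in expected lumen count per gland (Poisson with means
  2/6/12 for the default three classes labelled 33/44/55, one subclass
  per grade) and in texture amplitude (sd 4/8/12, aligned with grade):
  low-grade architecture is sparse and quiet, high-grade is lumen-rich
  and busy. The amplitude difference gives every window a class signal —
  with 2 expected lumens per 16-window gland, most low-grade windows
  contain no lumen, and lumen count alone could not support reliable
  per-window classification. The full 9-subclass label set
  {23, 32, 33, 34, 43, 44, 45, 53, 55} is supported by supplying
  per-class parameter vectors.
* Per-pixel Gaussian noise (sd 2) and integer quantisation complete the
  image; the default desk scale is 200-px glands, 2 images x 5 glands
  per class, with disjoint 50-px windows (16 per gland).

Under these conditions the class-average `mean_life_dim1` increases
strictly with lumen count, while the class-average `entropy_dim1`
*decreases* strictly. The decrease is forced by the entropy definition:
persistent entropy is maximal when all bars have equal length, so adding
dominant long-lived lumen bars to the roughly class-independent
population of short texture bars concentrates the lifetime distribution
and lowers H. An increase could only occur if the background contributed
essentially no bars at all, a regime in which windows without lumens
would carry no class signal whatsoever. Both monotone directions are
asserted in the test suite as the generator's class signature.

## What passing tests do and do not show

The generator reproduces the *topological statistics* the classifier
consumes — counts and lifetimes of components and loops, their window
distributions — not phase-imaging optics, stain variation, nuclear
texture, gland segmentation error, or the intra-class heterogeneity of
real tissue. End-to-end recovery of synthetic classes (gland-level
accuracy at or near 100%, macro AUC ~0.94 at the default conditions,
chance-level accuracy after gland-label permutation) demonstrates that
the pipeline's plumbing is sound and its features carry the intended
architectural signal; it does not validate clinical performance on
tissue.

# Problem sizes

The package's own runs use the desk-scale defaults: 30 glands of
200 px, 480 windows of 50 px, 5-fold CV with 5–10 repeats, and the
persistence oracle cross-check on 200 random images up to 8 x 8 over all
filtration levels. The survey-scale geometry (1,000-px glands, hundreds
of images, 100 repeats) is configurable but not exercised by the test
suite.

# Known limitations

* No gland segmentation: inputs are pre-cropped gland images or a
  whole image plus an integer label mask; mask-based extraction filters
  windows by in-mask coverage only.
* No superlevel or dual filtrations; bright-on-dark architecture should
  be analysed by inverting intensities first.
* No persistence in dimension 2 (always trivial here), no persistence
  landscapes/images; the descriptor is deliberately the 8 summary
  statistics.
* The decision tree's coarse probability scores cap its AUC below its
  accuracy; forests or LDA give smoother scores on the same features.
* Synthetic class separations are stated assumptions about gland
  architecture, not measurements of prostate tissue.
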