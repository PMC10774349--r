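---
title: "Recursive ensemble feature selection for microbiome signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive ensemble feature selection for microbiome signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control 16S rRNA amplicon studies produce a count matrix of samples
by amplicon sequence variants (ASVs) — exact denoised sequences resolved
to single-nucleotide differences — together with a binary phenotype.
Individual differential-abundance tests on such data rarely replicate
across cohorts: the data are compositional, overdispersed,
high-dimensional, and confounded by lifestyle and geography. `refsig`
takes the multivariate route: find the *smallest set* of ASVs that, as a
community, discriminates cases from controls, then ask whether that set
still discriminates in independent cohorts that were sequenced with
different primers and read lengths.

The package implements the full workflow: recursive ensemble feature
selection (REFS) for discovery, a disjoint five-classifier panel for
held-out evaluation, exact-subsequence matching for cross-cohort
transfer, standardized differential-abundance summaries, and a
Dirichlet-multinomial simulator that provides ground truth for all of it.

## Recursive ensemble feature selection

The count matrix is z-score normalized per ASV — population (1/n)
standard deviation, constant columns mapped to zero — and handed to an
ensemble of eight classifiers: a stochastic-gradient-descent linear
classifier, a linear support-vector classifier, gradient boosting, a
random forest, logistic regression, a passive-aggressive classifier, a
ridge classifier, and bagged decision trees. Under stratified ten-fold
cross-validation each member is fitted on the training fold and asked for
a per-feature importance: `|coefficient|` for the five linear members,
impurity importance for the forest and the bagged trees, split-gain
importance for boosting. Each member's importance vector is L1-normalized
before averaging, so a member whose importances live on a different scale
cannot dominate the consensus; the ensemble importance is the mean over
all fold-by-member vectors and itself sums to one.

Each elimination cycle records the mean held-out accuracy of the ensemble
and then removes the least important 20% of the surviving features (at
least one), iterating until a single feature remains:

    n_{k+1} = n_k - max(1, floor(0.2 * n_k))

Starting from 2040 features this schedule passes through 26 — the
signature size the procedure is known for. Because a single trajectory
depends on fold luck, the whole procedure is repeated as `n_runs`
independently seeded runs; the signature is the retained set of the
best-scoring cycle of the best run, ordered by decreasing ensemble
importance.

Three decisions here were genuinely open and are worth recording:

* **Cycle score.** Mean held-out *accuracy* across the fold-by-member
  grid drives cycle selection; ROC AUC is recorded alongside and reported
  by the validation module. The two orderings rarely disagree, but
  accuracy is the quantity the elimination loop optimizes here.
* **Tie-breaks.** Equal cycle scores resolve toward *fewer* features
  (parsimony); equal run scores resolve toward the lower run index. A
  consequence worth knowing: with a very strong signal the accuracy curve
  can plateau, and the parsimony rule then prefers small, pure subsets —
  so the *size* of the selected set is not a monotone readout of signal
  strength, only its ranking quality is (the test suite checks
  monotonicity on the importance ranking for exactly this reason).
* **Normalization order.** Scaling is fitted on the full matrix before
  cross-validation, which is the procedure's published order but leaks
  test-fold means into training. `fold_safe_scaling = TRUE` switches
  every consumer to training-fold-only statistics; the default emits a
  message naming the leak so nobody inherits it silently.

Member hyperparameters are frozen in `refs_ensemble_spec()` (and
`validation_classifier_spec()`), not exposed as tuning knobs: gradient
boosting uses 50 depth-3 trees at learning rate 0.1, the forest 100
trees, bagging 10 full-width trees (`mtry = p`), the linear online
learners run a fixed number of epochs with standard regularization
(Pegasos SGD with lambda = 1e-4, PA-I with C = 1, ridge with alpha = 1,
L2-logistic with lambda = 1/n). The one adaptive parameter is the MLP
hidden width in the validation panel: the BFGS optimizer behind `nnet` is
quadratic in the weight count, so the width is capped to keep roughly
2000 weights (32 units for signature-sized inputs, shrinking only for
very wide pre-selection matrices).

## Held-out validation

A signature is evaluated by classifiers that had no part in selecting it:
AdaBoost (SAMME on decision stumps), extremely randomized trees,
k-nearest neighbours (k = 5), a single-hidden-layer MLP, and
cross-validated lasso regression. The lasso is a regression learner used
as a ranker — ROC AUC needs only an ordering, so its continuous
prediction against 0/1-coded labels is used directly and no threshold is
ever chosen. Per classifier the report carries the mean and standard
deviation of the ten fold AUCs (the per-cohort table shape) and the ROC
of the scores pooled across folds (the figure shape); the five-classifier
mean is the headline number. Fold assignment is stratified and keyed to
*sorted* sample identifiers, which makes every report invariant to the
row order of the input files.

AUC itself is computed as the trapezoidal area under the empirical ROC
with tied scores collapsed, which is numerically identical to the
Mann-Whitney concordant-pair statistic with half credit for ties; the
test suite holds the two routes together at 1e-9 on random score vectors.

## Cross-cohort transfer by exact subsequence matching

Validation cohorts are typically sequenced with longer reads or different
hypervariable regions, so a discovery ASV cannot be looked up by
identity. Instead a signature ASV counts as present in a cohort when its
sequence occurs *verbatim* inside at least one of the cohort's ASV
sequences; the counts of all containing ASVs are summed and treated as
one feature. Two policies needed deciding:

* A validation ASV that contains two distinct signature sequences
  contributes its counts to both aggregated columns. Aggregation is
  defined per signature ASV; the report flags such shared hosts.
* Matching is forward-strand and case-insensitive by default (`U`
  becomes `T` on load). Cohorts processed in opposite orientation can set
  `rc = TRUE` to search the reverse complement as well; a hit on either
  orientation counts once.

Matching is a plain fixed-string scan — at ASV scale (thousands of
sequences, 150-300 nt) nothing faster is warranted, and the test suite
pins the scan to an independent character-by-character oracle.

## The synthetic study system

The simulator provides what the real study cannot: ground truth. Counts
follow a Dirichlet-multinomial — for each sample a library size is drawn
from a shifted Poisson (minimum 1000, mean 10,000 by default), a
composition from a Dirichlet over a log-normal baseline abundance profile
scaled to a total concentration (`overdispersion`, default 200; smaller
is noisier), and counts from the corresponding multinomial. A planted set
of informative ASVs has its concentration multiplied by
`exp(±effect_size/2)` per group, so the expected case:control
relative-abundance ratio is about `exp(effect_size)`; the effect sits on
the Dirichlet scale, keeping library-size variation orthogonal to the
signal. A configurable fraction of informative ASVs (default 15%, the
approximate share of the published signature reported absent from one
group) has its concentration *zeroed* in the depleted group — absence is
generative, not post-hoc masking. Defaults mirror the discovery study
design: 60 cases, 57 controls, 2040 ASVs, a 26-ASV planted signature,
150 nt reads.

The validation generator draws an independent cohort from the same
generative law, with longer reads (250 nt by default): for each retained
informative ASV, its counterpart validation ASV — plus up to two
additional hosts, emulating closely related bacteria sharing the amplicon
— receives a sequence containing the discovery sequence verbatim at a
random offset, each host used at most once so embeddings can never
overwrite one another. A `drop_fraction` of signature ASVs gets no
containing host at all, emulating the "No" rows of a presence table. The
containment map is self-verifying: an independent substring scan of the
generated sequences recovers it exactly, and the tests do exactly that.

Each generator call seeds one RNG stream from its config; counts are
drawn before sequences, so every output is bit-reproducible from the
seed. What the simulator deliberately does not emulate: taxonomic
structure, chimeras, read-level error, rank correlation between ASVs
beyond compositional coupling, and cohort-level batch effects. Passing
tests on this system therefore demonstrate that the machinery is correct
and well calibrated — not that any particular real dataset carries a
recoverable signature.

## Problem sizes and calibration

The benchmark the tests and the acceptance script run is a scaled-down
study: 200 samples by 500 ASVs with 15 informative ASVs at effect 2, five
REFS runs of ten-fold cross-validation. At this size the package recovers
93-100% of the planted ASVs, transfers the signature to an independent
cohort at a five-classifier mean AUC above 0.99, and collapses to
0.52-0.56 when labels are permuted — comfortably inside the
chance band. These sizes are the package's reference conditions for
reproducible numbers; the algorithms themselves carry no size
assumptions beyond at least two samples per class.

## Degenerate inputs and numerical conventions

* Constant (zero-variance) features standardize to zero rather than NaN.
* A class smaller than the fold count reduces the fold count to the class
  size with a warning; fewer than two samples per class is an error.
* The final elimination cycle has one feature; learners that require two
  columns are fitted with a constant zero pad whose importance is
  discarded.
* Importance vectors are clamped at zero and L1-normalized; a member
  whose importance degenerates to all-zero simply drops out of that
  fold's average.
* Elimination ties (equal importances) break by current column position,
  keeping runs deterministic.
* All randomness flows from one master seed through a deterministic
  integer derivation; replicate runs are seeded by run index and merged
  by index, so results cannot depend on execution order.

## Limitations

The published signature table ships without nucleotide sequences (they
were never published), so cross-cohort matching against real cohorts
cannot be reproduced from the packaged data — it is exercised end-to-end
on the synthetic system instead. Real-data performance numbers depend on
upstream denoising (DADA2 parameter choices, chimera removal) that is out
of scope here; the package consumes already-denoised count tables.
Binary phenotypes only; no covariate adjustment; no compositional
differential-abundance testing (the abundance module summarizes and
plots, it does not test).
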