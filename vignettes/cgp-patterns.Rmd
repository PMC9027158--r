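---
title: "Cyclic-group patterns for signal classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic-group patterns for signal classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpat)
```

## The problem

Resting-state EEG classification — for example separating schizophrenia
patients from healthy controls — is commonly attacked with hand-crafted
textural descriptors: cheap, deterministic features computed per channel,
followed by feature selection, a shallow classifier and an ensemble step
across channels.  `cgpat` implements one such pipeline end to end, with a
feature extractor whose comparison geometry is derived from number
theory rather than chosen ad hoc.

## The pattern extractor

For a prime modulus $p$ (default 17), every primitive root $a$ generates
the full multiplicative group: $a^1, a^2, \dots, a^{p-1} \pmod p$ is a
permutation $G$ of $\{1, \dots, p-1\}$.  The modulus 17 has exactly eight
primitive roots, hence eight generator sequences.

Each sequence defines one *center-symmetric local binary pattern*.  A
window of $p-1 = 16$ consecutive samples slides over the signal with
stride 1.  Within a window $b$, pattern $h$ compares the entries at
positions $G_h(k)$ and $G_h(p-k)$ for $k = 1, \dots, 8$:

$$\mathrm{bit}_k = \begin{cases} 1 & b(G_h(k)) - b(G_h(p-k)) \ge 0 \\
0 & \text{otherwise} \end{cases},
\qquad \mathrm{code} = \sum_{k=1}^{8} \mathrm{bit}_k\, 2^{k-1} .$$

The pairing is center-symmetric in the group: since
$G_h(k)\,G_h(p-k) \equiv a_h \pmod p$, the two compared positions are
always multiplicative complements, and across the eight pairs of one
group every window position is used exactly once.  Each bit position $k$
contributes weight $2^{k-1}$ — the standard binary-pattern weighting —
so the eight bits span codes $0\ldots255$ and each pattern yields a
256-bin histogram of code counts per signal.  Eight patterns give
$8 \times 256 = 2048$ features per signal.

Ties are resolved by the $\ge 0$ convention: a zero difference counts as
a 1-bit.  A constant signal therefore produces code 255 in every window,
a useful degenerate-input check.

### Multilevel decomposition

Before extraction, the signal is decomposed by *maximum absolute
pooling* (MAP): block size $b$ replaces each consecutive non-overlapping
block of $b$ samples by its largest absolute value, dropping a trailing
partial block.  Pooled signals $D_t = \mathrm{MAP}(x, 2^t)$, $t = 1,2,3$,
are each computed from the raw signal (not cascaded).  Extraction runs
on the raw signal and on $D_1, D_2, D_3$, and the four 2048-vectors are
concatenated into the merged 8192-dimensional descriptor.  MAP is a
contraction (its output never exceeds the input's maximum absolute
value) and preserves constancy, both of which are property-tested.

Histograms are kept as raw counts.  All segments of one configuration
have the same length, so counts and frequencies differ only by a common
factor, and the classifier standardizes every feature anyway.

## Segmentation

Records are cut into non-overlapping segments of 6250 samples (25 s at
250 Hz) by default; a trailing remainder is discarded.  Each segment
inherits its record's subject id and class label.

## Feature selection

`nca_weights()` implements diagonal neighborhood component analysis:
feature weights $w$ are fitted by maximizing the expected leave-one-out
accuracy of a stochastic nearest-neighbor classifier,

$$\max_w \sum_i \sum_{j : y_j = y_i} p_{ij}(w) - \lambda \lVert w\rVert^2,
\qquad p_{ij} \propto \exp\!\big(-d_w(x_i, x_j)/s\big),$$

with $d_w$ the squared Euclidean distance after scaling feature $f$ by
$w_f$.  Numerical choices, all fixed for reproducibility:

* features are standardized to zero mean, unit variance before fitting
  (constant features get a unit divisor);
* the softmax length scale $s$ is frozen at the mean pairwise squared
  distance of the standardized data.  Without it, distances grow
  linearly in the feature count and the soft assignment collapses to a
  hard nearest neighbor before optimization starts;
* full-batch gradient ascent, 60 iterations by default, with a
  multiplicative step adaptation (grow 5% on improvement, halve on a
  decrease).  The gradient is assembled from matrix products, so the
  per-iteration cost is one $n \times n \times d$ multiply;
* $\lambda = 1/n$, a conventional default for this estimator;
* returned weights are the squared fitted scalings, hence nonnegative.

`inca_select()` then ranks features by descending weight and scores
every prefix size in a candidate range (100–1000 by default, clamped to
the available feature count — 901 candidate subsets at the defaults) by
the misclassification rate of 1-NN under stratified 10-fold
cross-validation, growing the pairwise distance matrix one ranked
feature at a time so the sweep is linear in the range.  The minimizing
size wins; ties go to the smaller subset.

## Classification and validation

The classifier is 1-nearest-neighbor with Euclidean distance on
features standardized by the *training* statistics only; distance ties
go to the lowest training index.  Two validation schemes are built in:

* **10-fold** (`crossval_10fold`): stratified at the segment level.
  When a subject contributes several segments, they can span training
  and test folds — the scheme is reproduced as commonly practiced, but
  it is leaky by construction.
* **LOSO** (`crossval_loso`): one round per subject, all of a subject's
  segments held out together.  Train and test never share a subject;
  this is the honest generalization estimate for subject-level claims.

Metrics are accuracy, sensitivity, specificity and their geometric mean
$\sqrt{\mathrm{sen}\cdot\mathrm{spe}}$, with class 1 (the case class) as
the positive class by default — this is configurable, since the choice
is a convention.  Empty classes yield flagged `NA`s, never silent zeros.

## Channel fusion

`ihmv()` ranks channels by individual accuracy and, for each ensemble
size $c$ from `c_min` (default 3) to the channel count, votes per
segment by the mode of the top-$c$ channels' predictions.  The size with
the best voted accuracy is kept.  Deterministic tie-breaks throughout:
accuracy ties keep the lower channel index, mode ties take the smaller
label, best-size ties take the smaller ensemble.  The mode tie-break for
even ensembles is a genuine free choice; the smaller label mirrors the
usual mode semantics and is documented rather than hidden.

## Selection leakage, and the nested mode

The flat pipeline (`run_pipeline()`) applies feature selection once to
the full data and then cross-validates on the selected columns — the
common practice in hand-crafted feature pipelines.  With 8192 features
and desk-scale sample counts this is *strongly* optimistic: selection
sees the test labels, and on pure-noise data the flat pipeline can reach
near-perfect 10-fold accuracy.  `crossval_nested()` therefore refits the
entire selection inside every training split; its held-out predictions
measure genuine generalization.  The package's statistical tests use the
nested mode for null-calibration and leakage-gap checks, and the flat
mode (kept as the faithful default) for the separable-cohort benchmark.
Fold seeds for selection and evaluation are independent either way.

## The surrogate generator

`simulate_dataset()` emulates the *shape* of a resting-state EEG cohort
— two balanced classes of subjects, 19 channels at 250 Hz by default —
without claiming physiological realism.  Each channel is an AR(2)
resonance (pole radius 0.97, a sharp but stable spectral peak) scaled to
amplitude 2 against unit-variance white noise.  Class 0 peaks at 9 Hz,
an alpha-band rhythm; class 1 at $9 + \mathrm{effect\_size}\cdot 2$ Hz.
`subject_sd` perturbs each subject's peak frequency (in Hz), emulating
individual-rhythm variation: segments of one subject then share a
spectral fingerprint carrying no class information.  An amplitude offset
would not work for this purpose — the sign-comparison features are
invariant to positive affine transforms of the signal — so the subject
effect acts on the spectral parameter.

What passing tests show, and what they do not: the generator produces
stationary, artifact-free, spatially independent channels.  Success on
it demonstrates that the pipeline's machinery is correct and that its
validation schemes behave as theory predicts (chance-level nested
accuracy at zero effect; a 10-fold vs. LOSO gap under subject
contamination; near-perfect accuracy for well-separated spectra).  It
does not establish clinical performance on real recordings, which add
artifacts, volume conduction, nonstationarity and montage effects.

## Problem sizes used by the test-suite

The statistical checks run at desk scale, chosen once: 14 subjects per
class with two 25 s segments each (56 segments) for the separable and
contaminated cohorts, 28 subjects per class with one segment each for
the null calibration (one segment per subject removes within-subject
dependence, isolating the question "does the pipeline hallucinate class
signal?"), and 3–5 channels where channel count is not the property
under test.  Binomial 99% bands around 0.5 are used for chance-level
assertions.

## Known limitations

* The NCA optimizer is a fixed-iteration gradient ascent; it is
  deterministic and adequate for ranking, but no convergence guarantee
  is claimed.
* `subject_sd` models subject heterogeneity through one parameter
  (peak frequency); real inter-subject variability is far richer.
* The generalized modulus is restricted to $(p-1)/2 \le 16$ so code
  histograms stay at most $2^{16}$ bins; the tested configuration is
  $p = 17$.
* The flat pipeline's 10-fold numbers are estimates of the same leaky
  quantity practitioners usually report, not of generalization; use the
  LOSO columns or the nested mode for honest claims.
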