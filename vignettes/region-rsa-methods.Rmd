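---
title: "Region-based decoding and RSA: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based decoding and RSA: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(megrsa)
```

This vignette is the package's own account of the science it implements:
what the pipeline assumes, which knobs matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design choices
were settled.

## The analysis model

The pipeline treats source-space MEG as a collection of regional
multivariate signals. A cortical parcellation (82 bilateral regions of a
modified Destrieux scheme; `load_region_table()`) assigns every source
vertex to one region. Within a region, activity is assumed to be
well-summarized by a small number of fixed spatial patterns: we keep the top
**three spatial principal components** of the vertex × (time · trials)
matrix, fitted once per subject-region on all conditions jointly after
vertex-mean centring. Keeping a fixed 3-dimensional basis (rather than,
say, the regional mean) preserves within-region pattern structure while
making the classifier's feature space identical across conditions and time.

Decoding is pairwise and time-resolved. For two conditions, each with 10
pseudo-trials (averages of 5–8 raw trials), a two-class linear discriminant
with pooled within-class covariance is trained on 18 pseudo-trials and
tested on the 2 held out, at every 10-ms bin independently. Accuracy over
100 re-randomizations is both the performance measure and the dissimilarity
entry `d(a, b)` of the empirical RDM. Using accuracy (not d′ or crossnobis
distances) keeps the dissimilarity bounded and directly interpretable, at
the cost of ceiling effects for very strong signals.

The three binary model-RDM types formalize distinct hypotheses over the 12
entries (6 stimuli × 2 sections):

* **Stimulus recognizer** — any two different stimuli are dissimilar; the
  same stimulus across sections is similar. Sensitive to any reproducible
  stimulus-specific activity, meaningful or not.
* **Category-vs-nonsense** (face or tool) — dissimilarity across the
  category boundary exceeds dissimilarity within it; the other meaningful
  category is excluded entirely, and same-stimulus cross-section cells are
  masked so that mere stimulus identity cannot drive the correlation.
* **One-vs-rest** (face, tool, or meaningful-vs-nonsense) — one group
  against everything else, again with all same-stimulus cross-section cells
  masked. This is the instrument for *category-specific* activity: a face
  effect that is really just "meaningfulness" correlates equally with the
  face and tool variants, whereas a genuinely face-specific pattern
  correlates only with the face variant.

Model fit is Spearman correlation (average ranks — decoding accuracies from
200 test classifications tie often) over cells valid in both matrices,
Fisher-transformed for variance stabilization. Group inference is
mass-univariate: a one-sample t-test per region-time cell on the subject
z values, Benjamini–Hochberg FDR pooled over the full region × time grid
per model, and onsets defined as the first significant post-stimulus bin.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| analysis window | −100…700 | ms | covers baseline and the stimulus-on period at 81 bins |
| bin width | 10 | ms | 10:1 reduction of 1 kHz data; the finest resolution reported |
| components per region | 3 | — | smallest basis that retains pattern geometry; regions need ≥ 3 vertices |
| pseudo-trials | 10 | per condition | 18/2 train/test split; group sizes 5–8 for 50–80 trials |
| min trials | 50 | per condition | below this the pseudo-trial averages get too noisy; condition excluded, subject kept |
| randomizations | 100 | per pair | averages out the pseudo-trial composition; tests use 20 for speed |
| ridge λ | 10⁻³ | fraction of tr(Σ)/3 | 18 points in 3 dimensions is usually well-posed; the ridge only guards degenerate draws |
| FDR q | 0.01 / 0.05 | — | stricter for the high-SNR type 1–2 models, 0.05 for the type 3 contrasts |
| bootstrap | 1000 | resamples | percentile 95% CI of the across-subject mean; reject when 0 is outside |
| segments | 10 | per section | sequential blocks of 5–8 trials in presentation order |

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the *statistical structure* the analysis
assumes: 6 stimuli in 3 groups × 2 sections × up to 80 trials, regions with
variable vertex counts, additive region-confined effects (stimulus-specific,
category-binding with exemplar jitter, supra-categorical, repetition trends
with exactly linear segment means), i.i.d. Gaussian vertex noise with
optional temporal smoothing, and an optional region-level spatial-leakage
mix standing in for inverse-solution blur. Every injected effect is recorded
in a ground-truth manifest, which is what makes recovery testing possible.

It does **not** emulate: a forward model or lead fields, realistic cortical
geometry or noise covariance (MEG noise is spatially correlated and
non-stationary), eye/muscle artifacts, behavioral errors, or between-subject
anatomical variability beyond independent random effect loadings. Passing
recovery tests therefore demonstrates that the *pipeline* is correct and
calibrated under its own assumptions — not that those assumptions hold for
any particular recording. Amplitudes in the simulator are free parameters
chosen to make recovery well-posed; they are not estimates of real effect
sizes.

A note on the temporal envelope: injected effects use a raised-cosine (Hann)
taper sampled at *bin centres*, `sin²(π(i − ½)/N)` over the N bins of the
window. An endpoint-zero cosine would vanish entirely on windows only one or
two bins wide (e.g. 210–220 ms at 10-ms resolution); bin-centre sampling
keeps narrow windows energetic while remaining smooth and band-limited in
spirit.

## Numerical and procedural choices

* **Randomization coupling.** Each of the 100 decoder randomizations
  re-draws the pseudo-trial composition *and* the held-out pair. The
  alternatives (fixed composition, exhaustive hold-out) are subsumed by this
  choice, which maximizes effective resampling; it is applied uniformly.
* **Loading conventions.** Component loadings are fitted on both sections
  jointly (a per-section basis would make the feature spaces incommensurate
  across the section boundary) and sign-fixed so the largest-magnitude
  vertex loading is positive, making boundary weights reproducible.
* **LDA details.** Pooled within-class covariance over the 18 training
  pseudo-trials, ridge `λ·tr(S)/3·I`; a fully degenerate draw falls back to
  the mean-difference direction rather than failing. Classification ties
  (discriminant exactly 0) are resolved toward the second class; no special
  handling of accuracy ties at 0.5.
* **Fisher clipping.** `|ρ| = 1` is clipped to `1 − 10⁻⁶` before `atanh`.
* **Degenerate cells.** Zero variance across subjects yields `p = 0` when
  the mean is nonzero and `p = 1` otherwise, flagged, never an error.
  Undefined correlations (fewer than 3 joint cells, constant vectors)
  propagate as `NA` — missing, not zero — so excluded conditions mask cells
  without dropping subjects.
* **Sidedness.** The region-time t-tests are two-sided by default although
  the substantive hypotheses are directional; `one_sided = TRUE` is
  provided and is what the recovery analyses use, since a one-vs-rest model
  evaluated where a *different* category's effect lives has a slightly
  *negative* expected correlation (the model assigns 0 to cells the foreign
  effect makes highly decodable). A two-sided test would, with enough
  subjects, flag that construction artifact; the directional test asks the
  intended question.
* **MANOVA statistic.** Model specificity is tested with Bartlett's
  sequential dimensionality statistic at `d = 1` — rejection means the
  model-group means do not lie on one line — with
  `df = (p − d)(g − d − 1)`, i.e. 40 for 41 areas and 3 models. The model
  groups are treated as independent samples even though they share
  subjects; the result object carries a note, and a rank-deficient
  within-group scatter is handled by a pseudo-inverse on its support with
  df based on the effective rank (flagged).
* **Repetition analysis.** Boundary weights for a category are the
  renormalized mean of the unit discriminant normals over all of that
  category's exemplar-vs-nonsense pair classifiers and over the bins of the
  category window — exactly the classifiers that define the pattern being
  tracked. Only the first section is analyzed by default (`section` is an
  argument). The absolute value is taken *after* averaging over window and
  exemplars, which makes amplitudes invariant to a global sign flip of the
  weights. The regression pools all subject-segment points (10·n − 2
  residual df) rather than averaging per-subject slopes.
* **Seeding.** One master seed fans out to per-subject, per-stage streams
  via a stable keyed derivation (`derive_seed()`), so results are identical
  regardless of subject processing order or region subsets.

## Problem sizes used by the validation suite

The package's tests exercise the pipeline at deliberately small sizes:
null calibration at 8 subjects × 20 regions × 12 conditions × 50 trials with
20 randomizations (plus 100 reduced-size null replicates for the FDR
false-positive fraction), effect recovery over 20 replicates at 6 subjects ×
8 regions, and repetition-trend recovery over 20 replicates at 6 subjects ×
4 regions. These sizes give tight Monte-Carlo error on the quantities being
checked (chance level, FDR fraction, onset bins, slope signs) while keeping
the suite fast; they are validation designs, not recommendations for real
studies.

## Known limitations

* Accuracy saturates at 1, so very strong effects compress RDM structure;
  rank correlation mitigates but does not remove this.
* BH-FDR assumes positive dependence across cells; region-time statistics
  are smooth and positively correlated, which is the benign case, but no
  cluster-level inference is provided.
* The bootstrap test of characteristics is percentile-based and mildly
  anti-conservative for very small subject counts.
* The Bartlett test at full size (41 areas, 66 observations) estimates a
  41 × 41 scatter from 63 residual df; it is valid but low-powered, and the
  independence caveat above applies.
* No searchlight over vertices, no multiclass decoding, no continuous model
  RDMs, no noise-ceiling estimation.
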