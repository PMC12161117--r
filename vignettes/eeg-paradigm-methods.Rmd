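---
title: "Methods: paradigm-dependent EEG biomarkers for bipolar depression"
author: "eegparadigm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paradigm-dependent EEG biomarkers for bipolar depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Resting-state and passive-viewing EEG differs measurably between people
with bipolar depression (BD) and healthy controls (HC), but how strongly
depends on the recording *paradigm*: eyes closed, eyes open, or free
viewing of a video. `eegparadigm` implements a complete pipeline that
quantifies this paradigm dependence on three axes:

1. **functional connectivity** — per-band phase lag index (PLI) matrices
   over the 19-electrode 10–20 montage, compared edgewise between groups
   with FDR control;
2. **feature significance and cognitive relevance** — twelve per-channel
   feature families, tested per electrode between groups and correlated
   with four neuropsychological scores (TMT-A, TMT-B, DST, SDMT);
3. **classification** — a benchmark of six classical machine-learning
   classifiers discriminating BD from HC per paradigm.

Because clinical EEG recordings of this kind are not publicly
distributable, the package is validated through a first-class synthetic
cohort generator with known ground truth, so every downstream stage has a
parameter-recovery test.

## Preprocessing chain

Recordings (19 channels restricted from any larger montage, 250 samples/s)
are processed as:

* **average re-reference** — the instantaneous channel mean is subtracted;
* **broadband filter** — zero-phase Butterworth band-pass 1–49 Hz plus a
  second-order IIR notch at 50 Hz (Q = 30). Order 4 is applied
  forward–backward (effective order 8), standard EEG practice; the filter
  family is fixed, the order is our choice.
* **epoching** — non-overlapping contiguous 6-s epochs; the trailing
  remainder is discarded (epoch *k* covers `[6k, 6(k+1))` seconds);
* **band decomposition** — zero-phase Butterworth band-pass per canonical
  band: delta 1–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–49 Hz. The
  gamma band is capped at 49 Hz because the broadband filter removes
  everything above it.

Numerical details that matter:

* Filtering uses odd-reflection padding with steady-state initial
  conditions (the `lfilter_zi` construction) at both ends of each
  forward–backward pass; epochs get 1 s of padding per side, continuous
  recordings 3 s. This suppresses the start-up transient of the high-Q
  notch for all inputs except a signal that is itself coherent at the
  notch frequency near a recording edge — a re-locking transient intrinsic
  to every zero-phase IIR implementation (we verified bit-identical
  behaviour against an independent implementation of the same
  construction). Line-noise suppression is therefore specified, and
  tested, in steady state: a 50 Hz tone is attenuated below 1e-9 of its
  input RMS away from the first and last two seconds.
* The Hilbert analytic signal is computed per epoch via the
  frequency-domain construction; the first/last few samples of each epoch
  carry small phase distortions, which is why an end-to-end noiseless
  coupled pair reaches PLI ≈ 0.99 rather than exactly 1, while the PLI
  estimator itself is exactly 1 on constant-lag phases.

## Features

Twelve per-channel families (228 features over 19 channels):

* **band power (5)** — Welch periodogram per 6-s epoch (2-s Hamming
  segments, 50% overlap, one-sided density), integrated over `[low, high)`
  Hz and averaged across epochs. The estimator parameters are our choice;
  a unit tone at 10 Hz recovers its theoretical 0.5 µV² alpha power within
  2%.
* **differential entropy (5)** — Gaussian closed form
  `DE = 1/2 ln(2πe σ²)` in nats on the band-filtered epoch variance,
  averaged across epochs; on Gaussian signals this is monotonically
  related to log band power (a property test enforces Spearman ρ > 0.95).
* **delta→beta dPAC (1)** — debiased phase–amplitude coupling,
  `|mean(a e^{iφ}) − mean(a)·mean(e^{iφ})|` with delta phase φ and beta
  envelope *a* concatenated across epochs. The debiasing term removes the
  phase-clustering bias; an analytically tractable case (envelope
  `1 + κ cos φ`, uniform φ) gives κ/2, e.g. 0.45 at κ = 0.9. A variant
  normalised by the mean envelope is available (`normalize = TRUE`).
* **delta–beta AAC (1)** — Pearson correlation of the two Hilbert
  envelopes over concatenated samples. Concatenation (rather than
  per-epoch correlation averaging) stabilises the estimate on short
  epochs.

Features are averaged per subject by default; whether per-epoch
computation with later averaging would be preferable is not decidable from
first principles, and the per-epoch route can be assembled from the same
primitives.

## PLI connectivity

For channels *a, b*, the phase difference is wrapped to `(−π, π]` at every
sample and its sign (with `sgn(0) = 0`) averaged — over the samples of each
epoch, then across epochs — and the modulus taken at the end:

`PLI = | mean_epochs( mean_t sgn(Δφ_{a,b}(t)) ) |`

The trial/time semantics deserve a note: with equal-length epochs the
epoch-then-grand average equals the grand mean over all samples, and a
brute-force per-sample oracle pins the implementation to 1e-12. PLI is
insensitive to zero-lag coupling (volume conduction) because `sgn(0) = 0`,
which is why the identity-channel case yields 0, not 1. Estimation uses
the full 6-s epoch; sub-epoch windowing conventions are not modelled.

## Statistics

* **edgewise comparison** — two-sample rank-sum (Mann–Whitney) per edge;
  this is the correct nonparametric test for two *independent* groups of
  unequal size (28 vs 42). Exact enumeration for small tie-free samples,
  normal approximation with mid-ranks and tie correction otherwise.
  Benjamini–Hochberg correction is applied within band across the 171
  edges, matching per-band reporting; direction is the sign of the median
  difference.
* **feature tests** — per-cell independent-samples t-tests (pooled
  variance by default, Welch optional), flagged at p < 0.05 uncorrected to
  mirror common per-electrode reporting; a BH-corrected mode exists.
* **demographics** — Welch t from summary data (it reproduces printed
  age/YMRS/HAMD-24 statistics to 2 decimals; the pooled variant is kept as
  an option) and Pearson χ² without continuity correction.
* **cognition** — Spearman correlations (Pearson on mid-ranks,
  t-approximation p) between every feature cell and each of TMT-A, TMT-B,
  DST, SDMT, flagged at p < 0.05; per-paradigm significant-cell counts
  feed the paradigm ranking.

## Classifier benchmark

Six classifiers with fixed hyperparameters: AdaBoost.M1 on decision-tree
stumps (100 learners, written in-package as no installed library provides
AdaBoost on trees), KNN (k = 5), Gaussian naive Bayes, random forest (100
trees, √p features per split), linear SVM (C = 0.25) and a CART tree. The
tree controls (`minsplit = 5`, `minbucket = 2`) are sized for the small
cohorts this field works with, where the library defaults would refuse to
split at all.

The validation scheme is stratified 5-fold cross-validation with 10
repeats and **subject-level splits**: every row of one subject is confined
to a single fold, so epoch-level feature matrices cannot leak between
training and test. Features are z-scored using training-fold statistics
only. Accuracy and binary F1 (BD positive) are averaged over folds and
repeats; a majority-class baseline is reported alongside. Published
accuracies in this literature often suggest epoch-level evaluation, which
inflates performance through within-subject correlation — the subject-level
default is deliberately conservative.

## The synthetic cohort generator

`cohortSpec()` defaults encode the study conditions the analysis assumes:
28 BD and 42 HC subjects, 19 channels at 250 Hz, 180 s per paradigm.
Signals are sums over bands of narrowband Gaussian processes (white noise
band-filtered, so phases drift realistically — pure tones would give
degenerate Hilbert phases) over a 1/f background synthesised by spectral
shaping with exponent 1 (flat below 1 Hz). Band RMS amplitudes default to
δ 8, θ 5, α 10, β 3, γ 1.5 µV with an 8 µV 1/f floor — typical scalp EEG
magnitudes — and per-subject lognormal amplitude variation (σ = 0.3 on the
log scale) gives subjects trait-like power differences.

Coupling is injected per edge by mixing a shared narrowband source into
both channels, the second copy delayed in the frequency domain by
`lag/(2πf₀)` seconds (a fractional-sample delay; integer-sample delays at
250 Hz would quantise the lag). Mixing is variance-preserving
(`√(1−w²)`·own + `w`·shared), so `w = 1` yields a pure lagged copy and
PLI → 1. The default coupling graph mirrors the qualitative group
structure the analysis targets: stronger BD coupling in δ/θ/β/γ with eyes
closed, no group difference with eyes open, weaker BD δ/θ coupling during
free viewing; why paradigms differ mechanistically is not modelled — the
generator simply exposes per-paradigm overrides.

Cross-frequency coupling scales the β component's envelope by
`(1 + κ cos φ_δ)` (RMS-normalised); κ defaults to 0.4 (BD) vs 0.15 (HC).
Cognitive scores are drawn from a linear model on each subject's
*realized* (not nominal) eyes-closed δ/θ log band power, with intercepts
near typical test values (TMT-A 27 s, TMT-B 38 s, DST 13, SDMT 68) and
noise SDs chosen so the driver explains roughly half the score variance.
Every subject×paradigm stream derives from the master seed by a counter,
so partial regeneration is reproducible.

What the generator does **not** emulate: ocular/muscle artifacts (the
manual ICA step of clinical pipelines is out of scope), volume-conduction
head geometry, and nonstationarity beyond envelope modulation. Passing
parameter-recovery tests therefore demonstrates the estimators and
statistics are correct and calibrated on data satisfying their
assumptions — not that the pipeline is robust to artifacts real recordings
contain.

## Problem sizes used in the automated checks

The test suite and `scripts/acceptance.R` run everything from scratch, so
simulation sizes are chosen to make each check sharp but affordable:

* *edge recovery* — full study-size cohorts (28/42 subjects, 30 epochs)
  restricted to a δ-band + 1/f connectivity cohort with five coupled edges
  (strength 0.8 vs 0.2), 20 seeds in the test suite;
* *FDR control* — 200 null cohorts simulated at the connectivity-tensor
  level (the statistical layer is what the property concerns);
* *paradigm ranking* — reduced cohorts (6/6 subjects, 12 s, 3-fold CV)
  with the group effect injected only into the eyes-closed generator; the
  ranking property is scale-free;
* *closed forms* — 60-s single-channel signals.

## Known limitations

* The exact published dPAC/AAC constructions are cited rather than fully
  specified in this literature; the implemented debiased form is the
  standard one and is pinned by its closed-form oracle, but other variants
  exist (the normalised form is exposed as an option).
* The gamma band is bounded at 49 Hz by the broadband filter; studies
  using higher gamma would need a different front end.
* Rank-sum p-values for n = 28/42 use the normal approximation; exact
  enumeration is reserved for small samples.
* EDF support covers the single-rate, 16-bit core of the format — enough
  for scalp EEG interchange, not the full EDF+ annotation model.
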