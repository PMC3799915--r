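---
title: "Joint channel-specific FIR and spatial filtering for single-trial EEG decoding"
author: "ccssp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint channel-specific FIR and spatial filtering for single-trial EEG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccssp)
```

## The problem and the model

Common spatial patterns (CSP) is the workhorse feature extractor for
two-class single-trial EEG decoding: given trials $X \in \mathbb{R}^{C \times T}$
under two mental conditions, it finds spatial filters $w \in \mathbb{R}^{C}$
extremizing the variance ratio

$$\lambda(w) \;=\; \frac{w^\top \Sigma_1 w}{w^\top (\Sigma_1 + \Sigma_2) w},$$

where $\Sigma_c$ is the average (trace-normalized) covariance of condition
$c$. Because $w$ weights channels only, CSP is blind to spectral structure:
if two conditions differ in *which frequency band* is active on a channel
rather than in total channel power, no spatial filter can separate them.

This package implements the delay-embedding extension of CSP. Each channel
$c$ is convolved with its own FIR filter with taps $b^{(c)}_i$,
$i = -k, \dots, k$ (order $2k+1$, symmetric support), before spatial
weighting. Algebraically this is CSP on the *augmented* data
$\tilde{X} \in \mathbb{R}^{C(2k+1) \times (T - 2k)}$ obtained by stacking
the $2k+1$ time-shifted copies of every channel: a single augmented
eigenvector $\tilde{w}$ simultaneously encodes one spatial filter per delay
(read it in delay blocks) and one FIR filter per channel (read it across
blocks at a fixed channel). The two readings are exactly equivalent to
projecting the embedded data, an identity the test suite checks to
$10^{-10}$.

The augmented space has $D = C(2k+1)$ "channels" against only $T - 2k$
samples per trial, so the composite covariance is easily singular and the
eigenproblem ill-posed exactly when training data are scarce. The package
therefore solves the regularized problem

$$(\tilde{\Sigma}_1 + \varepsilon I)\, \tilde{w} \;=\;
  \lambda\, (\tilde{\Sigma}_1 + \tilde{\Sigma}_2 + 2\varepsilon I)\, \tilde{w},$$

with a scalar ridge $\varepsilon > 0$ on both sides. This placement keeps
the familiar CSP semantics: the denominator is positive definite for any
$\varepsilon > 0$, all eigenvalues are real and lie strictly in $(0, 1)$,
and swapping the two class roles maps the spectrum to its reversed
complement $1 - \lambda$. With $k = 0$ the whole construction reduces to
regularized conventional CSP, which the tests verify against an
independently coded reference to $10^{-10}$ in the features.

## Estimation choices

* **Covariances.** Per trial, the scatter $\tilde{X}\tilde{X}^\top$ is
  divided by its trace, then averaged within condition and renormalized to
  unit trace. Trace normalization per trial equalizes trial power before
  averaging — standard CSP practice — and makes a dataset-independent
  $\varepsilon$ grid meaningful, since $\varepsilon$ is applied on the
  trace-one scale. Conditions are defined by sorted stored labels (smaller
  label = condition 1), so 0/1-labeled files need no rewriting.
* **Eigensolver.** The right-hand matrix is Cholesky-factored and the
  problem reduced to a symmetric eigendecomposition in whitened
  coordinates. A singular composite matrix with $\varepsilon = 0$ is
  reported as an explicit error advising regularization rather than a
  silent least-squares fallback. Eigenvectors are returned with unit
  Euclidean norm and the sign fixed so each column's largest-magnitude
  entry is positive; both are free parameters of the eigenproblem and
  fixing them makes fits byte-reproducible.
* **Filter selection.** The model keeps $m$ columns with the largest
  eigenvalues (condition-1-maximal variance) and $m$ with the smallest,
  ordered descending then ascending. Defaults: $m = 3$ for oscillatory
  (motor-imagery-style) data, $m = 2$ for event-related-potential
  detection.
* **Features.** Natural log of the sample variance of each projected
  series. Features are *not* normalized across filters by default (a
  `normalize` flag provides the variance-share variant). A projected series
  with zero variance raises an error naming the trial and filter; flooring
  it to $-\infty$ would silently poison the classifier.

## Hyperparameters

| parameter | meaning | default | grid |
|---|---|---|---|
| $k$ | FIR half-order; filters have $2k+1$ taps | 5 | 0, 1, 3, 5 |
| $\varepsilon$ | ridge scalar on trace-one covariances | $10^{-5}$ | $10^{-4}, 10^{-5}, 10^{-6}$ |
| $m$ | filter pairs kept | 3 (oscillatory), 2 (ERP) | — |

The fixed defaults and the cross-validation grids mirror the two operating
modes the method is normally used in: a fixed parameterization applied to
all datasets, and per-dataset selection by stratified 5-fold
cross-validation (fold seed 0, independent of the grid). Ties in the mean
held-out score are broken toward smaller $k$, then larger $\varepsilon$ —
the simpler, more regularized model. With few trials and many channels the
cross-validated mode is the weaker one: model selection itself consumes
data, which is the documented drawback of the approach.

## Classifier and metric

Log-variance features go into a soft-margin linear SVM (unit base cost)
with per-class penalties inversely proportional to class frequency,
$w_c = n/(2 n_c)$, so a 41:4000 design penalizes minority errors about 98
times harder. The performance measure for imbalanced designs is balanced
accuracy — the mean of the two per-class recalls — whose chance level is
0.5 regardless of imbalance; an always-majority predictor scores exactly
0.5. For balanced designs plain accuracy coincides with it exactly. The
kernel and cost are deliberately left simple: 4–6 log-variance features are
near-linearly separable in this literature, and fewer knobs means less to
select on small data.

## Preprocessing recipes

Two named presets reproduce the standard recipes for the two paradigms:

* `mi`: 8–30 Hz fifth-order Butterworth bandpass on the cue-locked epochs
  (0.5–2.5 s window). Applied causally by default — a zero-phase flag
  exists, but the causal single pass is the conservative reading when the
  original description names only the filter.
* `rsvp`: 1 Hz high-pass applied twice, then 25 Hz low-pass, on the
  continuous recording, followed by segmentation into 0–500 ms
  event-locked windows. These are linear-phase windowed-sinc (Hamming) FIR
  filters applied forward-backward, with length chosen by the
  $3 f_s / f_c$ rule rounded up to even. The zero-phase choice is
  deliberate: the downstream 0–500 ms window is latency-sensitive, and a
  causal high-order FIR would shift the transient by half the filter
  length. This emulates, rather than replicates, the EEGLAB-style routine
  the recipe descends from.

Epoch windows are half-open $[t_0, t_1)$ with 1-based onset samples, giving
unambiguous sample counts (`round((t1 - t0) * fs)`).

Embedding keeps only the valid region (dropping $k$ samples at each end)
instead of zero-padding: padding injects spurious transients into the
covariance estimates, and $2k \ll T$ in every intended use.

## The synthetic generator

Real EEG is expensive and external recordings are not redistributable, so
every claim is exercised on synthetic data with known ground truth:

* *mi-like*: band-limited Gaussian sources (white noise passed through the
  package's own Butterworth bandpass, unit variance) with class-dependent
  amplitudes $\sqrt{r}$ vs $1/\sqrt{r}$, mixed to the channels by a loading
  matrix, plus white sensor noise.
* *rsvp-like*: white-noise trials where the rare class adds an odd-length
  half-sine transient (peak exactly on the latency sample) on a loaded
  channel subset.

Three canned scenarios fix the study conditions (`defaultBenchmarkSuite()`):
(a) a broadband 5–45 Hz power difference on one channel pair — purely
spatial structure where $k = 0$ suffices; (b) two narrow-band sources
(8–12 Hz and 18–22 Hz) on the *same* channel pair with opposite power
ratios 2 and 0.5, so total channel power is class-balanced and only
spectral filtering separates the classes; (c) 1:50 target:distractor
imbalance with a 300 ms, 200 ms-wide, amplitude-2 transient on three of
eight channels under unit noise. Sizes (6–8 channels, 120 trials per
mi-like draw, 1020 per rsvp-like draw, 100–250 Hz) are chosen as the
smallest configurations at which the three contrasts are cleanly expressed.

What the generator does **not** emulate: $1/f$ background spectra,
eye-blink/EMG artifacts, volume-conduction forward models, latency jitter,
or non-stationarity across a session. Passing tests therefore demonstrate
the *algorithmic* claims — band recovery, the CSP reduction, imbalance
handling — not field performance on real recordings.

## Numerical and degenerate-input policy

* Covariance symmetry is enforced to $10^{-12}$ and trace to 1; a
  zero-power trial is an error naming the trial.
* Near-singular composite matrices (Cholesky pivot below
  $\sqrt{\epsilon_{\mathrm{mach}} \cdot \mathrm{tr}}$) raise a numerical
  error rather than returning noise-dominated filters.
* All validation failures name the offending field; the command-line tool
  maps usage, data and numerical errors to exit codes 2, 3 and 4.
* All randomness flows through explicit seeds; two runs with identical
  flags produce byte-identical model and prediction files.

## Verification strategy

The suite checks each stage against something *other than itself*: closed
forms for the diagonal eigenproblem and FIR responses, an independently
coded regularized CSP for the $k = 0$ reduction, brute-force random-search
Rayleigh quotients for the solver (the search must never beat the solver's
extrema — with $10^5$ uniform directions in up to six dimensions the search
maximum itself stays up to a percent *below* the true optimum, so only
this one-sided comparison is statistically meaningful at tight tolerance),
hand-computed covariances, and the planted structure of the generator. The
scenario-level claims are measured on held-out draws over 10–20 seeds.

Known limitations: two conditions only; no shrinkage estimators beyond the
scalar ridge; no multiclass or online variants; interpretation outputs are
channel-weight tables, not scalp maps.
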