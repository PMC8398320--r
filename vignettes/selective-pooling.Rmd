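---
title: "Selective subject pooling for subject-independent motor-imagery BCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective subject pooling for subject-independent motor-imagery BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipool)
```

## The problem

A motor-imagery (MI) brain-computer interface decodes imagined left- versus
right-hand movement from EEG. Imagery attenuates the 8–13 Hz mu rhythm over
the motor cortex contralateral to the imagined hand (event-related
desynchronization, ERD), so the class-dependent quantity is oscillatory
*band power*, and the standard decoder stack is: band-pass filter, common
spatial patterns (CSP), log-variance features, linear discriminant analysis
(LDA).

Subject-specific (SS) decoders need a calibration session from every user.
Subject-independent (SI) decoders avoid calibration by training on other
subjects' pooled data, but a sizable fraction of users — commonly quoted as
10–30% — produce no decodable MI patterns at all ("BCI inefficiency"), and
their recordings degrade the pooled model. The package implements a
selective pooling rule: score every candidate source subject by their own
SS accuracy, and admit them to the training pool only if that accuracy
exceeds a statistically derived chance threshold.

## The models

### CSP

For classes 1 (left hand) and 2 (right hand), let $\Sigma_1, \Sigma_2$ be
the covariance matrices of the trial-concatenated, per-trial mean-centered,
band-pass filtered signals. `fitCSP()` solves the generalized eigenproblem

$$\Sigma_1 w = \lambda\,(\Sigma_1 + \Sigma_2)\, w,$$

normalized so that $W^\top(\Sigma_1+\Sigma_2)W = I$ and
$W^\top\Sigma_1 W = \mathrm{diag}(d)$ with $d$ descending in $[0,1]$. The
first columns maximize class-1 band power, the last maximize class-2 band
power; `selectFilters()` keeps the outer $m$ pairs (we use $m=2$ for SS and
$m=3$ for pooled training, matching common practice). Features are
$\log(v_j/\sum_k v_k)$ of the per-filter projected variances
(`cspFeatures()`), which makes them invariant to per-trial amplitude scale.

The implementation whitens $\Sigma_1+\Sigma_2$ and eigendecomposes the
whitened $\Sigma_1$; an independent oracle (direct eigensolve of
$(\Sigma_1+\Sigma_2)^{-1}\Sigma_1$) cross-checks it in the tests. Ties in
the eigenvalues are resolved by the symmetric eigensolver's deterministic
ordering, and every filter column is sign-normalized so its
largest-magnitude entry is positive. A rank-deficient composite covariance
is an error by default; an optional ridge (`ridge` argument, scaled by
trace/C) is available but off.

### Filter-bank CSP with MIBIFS

`fitFBCSP()` repeats CSP (2 pairs per band) over a fixed 15-band bank
(`makeFilterBank()`: 8–30, the four classical rhythms, and ten overlapping
6 Hz-wide bands), concatenates the 60 candidate features, and prunes them
by mutual-information best individual feature selection
(`mibifsSelect()`): features are ranked by estimated $I(\text{feature};
\text{class})$ and pairs are claimed down the ranking — each selected
feature brings the mirrored filter of its band — until `kPairs` (6, 10 or
20) pairs are kept. Mutual information uses a plug-in discrete estimator
on rank-based equal-frequency bins ($\lceil\sqrt N\rceil$ bins, capped at
16, configurable); the original FBCSP literature used Parzen windows, but
the discrete plug-in admits an exact brute-force oracle in the tests and
behaves equivalently for ranking purposes.

### Shrinkage LDA

`fitSLDA()` uses the pooled within-class covariance shrunk toward
$\nu I$ ($\nu$ = mean eigenvalue), with the intensity $\gamma$ chosen
analytically from the variances of the entrywise cross products
(a Ledoit–Wolf/Schäfer–Strimmer-type estimator, `shrinkageGamma()`),
clipped to $[0,1]$. The boundary sits at the midpoint of the projected
class means; scores of exactly zero go to class 1 (deterministic
tie-break). One degenerate case is worth knowing: at $n = 2$ the two
centered samples are mirror images, every cross-product variance vanishes,
and the analytic $\gamma$ is 0 — the estimator needs $n \ge 3$ to express
its small-sample behavior.

### Chance-level thresholds

For a classifier scored on $n$ trials with expected chance level $p_0$,
`chanceLimits()` returns the adjusted interval

$$p_0 \pm z_{1-\alpha/2}\sqrt{\frac{p_0(1-p_0)}{n+4}}.$$

With $p_0 = 0.5$, $n = 100$, $\alpha = 0.05$ the limits are
0.4039/0.5961. The upper limit is the pooling threshold: `buildPool()`
admits subjects whose SS accuracy is *strictly greater* (boundary-equal
accuracies are excluded — "greater than" read literally). $n$ is the
number of test trials of the protocol in use, both classes combined, and
no continuity correction is applied (the formula as stated). Threshold
comparisons use unrounded values throughout.

### Evaluation protocols

* `subjectSpecificEval()` — train and test within each subject.
* `losocv()` — leave-one-subject-out: pool = everyone (`strategy = "all"`)
  or the selective pool at a significance level. Pool membership is
  computed once from the full SS run; the evaluated subject is removed per
  fold (not re-thresholded), and an audit log records every fold's
  training subjects so exclusion is verifiable.
* `crossDatasetEval()` — one pooled model trained on dataset A, scored per
  subject of dataset B; montages must be harmonized (identical ordered
  channel lists) first.
* `subsampleTrials()` / `losocvSubtrials()` — balanced random sub-trial
  draws (default three repeats, seeds derived as base + repeat index, mean
  reported) for comparing trial-count regimes; the matching threshold then
  uses the subsampled trial count.
* `wilcoxonCompare()` — two-sided paired signed-rank test; zero
  differences dropped, exact null for up to 25 untied differences, and an
  all-zero comparison returns p = 1 flagged as degenerate.

If a fold's effective pool is empty, its accuracy is reported as `NA` with
a warning and excluded from the mean — silently skipping subjects would
bias comparisons.

Internally `losocv()` caches, per subject and band, the per-trial
covariance matrices and their class sums, so each fold's trial-concatenated
covariance is a weighted sum and each trial's log-variance feature a single
matrix product. This is algebraically identical to the naive
concatenate-and-refit path (`pooledTrain()`), which the tests assert.

## The synthetic population

`simulateSubject()` builds band-limited oscillatory EEG over a motor
montage: spatially correlated 1/f background noise (neighboring channels
correlated ~0.5) plus a mu oscillation (subject-specific peak in
8.5–12.5 Hz, weak second harmonic) radiating from two Gaussian sources at
C3 and C4. On left-hand trials the C4 source amplitude is multiplied by
$1-\texttt{erdDepth}$ (and C3 on right-hand trials); the "ipsilateral"
profile mostly swaps the attenuation side, keeping a weak normal residual,
since real anomalous subjects show mixed rather than perfectly inverted
patterns.

A population of such subjects with identical background statistics turned
out, during design, to be *too easy to pool*: CSP's whitening makes the
pooled decoder indifferent to class-symmetric, population-typical data, so
adding chance-level subjects was harmless and selective pooling showed no
advantage. The pooling phenomenon requires low-skill subjects to be
atypical, not merely uninformative, and the generator therefore links
skill to several literature-grounded signatures of BCI inefficiency:

* **per-subject idiosyncrasies (all subjects)** — jittered source
  positions and extents, random per-channel gains, a global amplitude
  factor (covariances pool unnormalized, so loud subjects weigh more), and
  a task-unrelated background alpha source at a random scalp location;
* **poor performers** (`erdDepth` ~ 0) — a much louder background alpha
  source (`bgScale` drawn from 4–6 versus ~1), and stronger erratic,
  cue-unrelated lateralized mu modulation;
* **session drift (all subjects)** — slow linear drift of oscillatory
  power across the session. Trials are laid out in class blocks, so drift
  is partially confounded with the labels and plants spurious,
  non-transferable class-covariance structure — a deliberate model of the
  block-design confound in real sessions.

The mu-source amplitude constant (0.8–1.2 times the noise scale after the
per-subject gain) was fixed once so that `erdDepth` spans realistic SS
accuracies: ≈0.5 at 0, ≈0.7 at 0.2, >0.9 from 0.5 upward. Ground-truth
profiles are attached to every simulated dataset
(`attr(d, "profiles")`) for recovery tests. All randomness derives from
one master seed via per-subject derived seeds, so identical specs give
byte-identical datasets regardless of execution order.

What the generator does **not** model: artifact waveforms (EOG/EMG),
volume-conduction forward physics, cross-session nonstationarity, and
heavy-tailed noise. Passing tests on this substrate show that the
pipeline's algebra, protocols and selection logic behave as designed and
that the pooling phenomenon emerges under realistic heterogeneity; they do
not certify effect sizes on any real dataset.

## Numerical and design choices

* Band-pass: 4th-order Butterworth applied forward-backward. The squared
  magnitude response is applied in the frequency domain with odd-reflection
  padding — exactly zero-phase, verified against time-domain
  forward-backward filtering, and fast enough to filter a whole subject in
  one FFT pair.
* Resampling: rational polyphase (zero-stuffing, Kaiser-windowed sinc,
  decimation) with group-delay compensation; integer ratios such as
  512→128 Hz are exact, and a 10 Hz sinusoid survives with <2% amplitude
  error.
* Windows are half-open $[t_0, t_1)$; sample $k$ sits at $t_0 + k/f_s$.
  Cropping 1.0–3.5 s gives 320 samples at 128 Hz and 250 at 100 Hz.
* Filtering is applied per epoch (fixtures are epoched), before cropping,
  so filter transients fall partly outside the analysis window.
* Labels are integers 1 (left hand) and 2 (right hand); the mapping is
  recorded in the fixture metadata. Fixtures are plain text (JSON +
  tab-separated tensors with 17 significant digits), which round-trips
  doubles bit-exactly and diffs cleanly under version control.

## Problem sizes used in the tests

The test suite exercises the full pipeline at desk scale: oracle checks on
4–8 channel instances; single-subject checks on a 6-channel motor strip
with 50 trials per class; the pooling-strategy comparison on twenty
populations of 20 subjects (60% good, 30% poor, 10% ipsilateral; 50 trials
per class per split; 20-channel montage); and parameter recovery on ten
5-good/5-poor populations. These sizes were chosen as the smallest at
which the population-level claims are statistically meaningful.

## Known limitations

* The selection criterion is classifier-dependent: SS accuracy under
  CSP-rLDA stands in for "produces decodable ERD". Subjects whose SS score
  is inflated by session confounds enter the pool and dilute it; the
  generator reproduces this failure mode deliberately.
* Strongly anomalous (ipsilateral) subjects pass any SS threshold yet harm
  transfer — a structural blind spot of accuracy-based selection, visible
  in the evaluation tables as below-chance accuracy for those subjects.
* The MI estimator, shrinkage variant and filter counts are configurable
  but the defaults follow the mainstream choices described above; no
  claim of optimality is made.
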