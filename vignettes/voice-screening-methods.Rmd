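---
title: "Methods: voice-based screening for cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voice-based screening for cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicescreen)
```

## The screen

`voicescreen` implements a ~20-second screen for cognitive decline
equivalent to dementia based entirely on a spoken response to a
time-orientation question (the current date and day of the week, Western
calendar). Three signals are combined: the speaker's age, the 0–4 score
of the orientation response, and acoustic features of how the response
was spoken. The underlying assumption is clinical: temporal orientation
is among the earliest domains affected in dementia, and speech in
cognitive decline is slower, more hesitant and more pause-laden — which
is precisely what low-frequency temporal modulation of the speech signal
measures.

## The acoustic model

The recording contract is mono RIFF WAV at 16 kHz; other rates are
band-limited-resampled (Fourier-domain) and multi-channel audio is
averaged to mono. Each utterance is power-normalized to a fixed RMS of
0.1 per utterance. "Power normalization" is deliberately RMS- rather
than peak-based: a single click would otherwise set the gain for the
whole utterance. The target level is arbitrary (any fixed level yields
features identical up to a constant log-power offset shared by all
utterances); 0.1 leaves ~20 dB of headroom before clipping in the
16-bit representation.

MFCCs use conventional settings for 16 kHz speech — 25 ms Hamming
frames, 10 ms hop, pre-emphasis 0.97, 26 triangular mel filters to
Nyquist, 13 orthonormal-DCT cepstra including c0 — all configurable via
`feature_config()`. None of these choices are critical: the downstream
feature integrates over the whole cepstrum.

The modulation spectrum of coefficient $j$ is

$$M_j(f) = \log\left|\mathcal{F}_t\{c_j(t) - \bar c_j\}\right|^2,$$

the log power spectrum of the coefficient's frame-level time series.
Design choices, in order of consequence:

* **Fixed analysis length** (512 frames ≈ 5.1 s at the 10 ms hop,
  zero-padded; longer trajectories are truncated with a warning). This
  fixes the modulation-bin grid (≈ 0.195 Hz spacing) so bins are
  comparable across utterances of different durations — essential when
  the bins themselves are the classifier features.
* **Mean removal before the DFT**, so the DC bin does not swamp the
  low-order region; DC is also excluded from the selected components.
* **Log floor** at $\varepsilon = 10^{-12}$, keeping silent coefficients
  finite (a constant trajectory floors the whole spectrum at
  $\log \varepsilon$).
* **Aggregation**: the feature vector is the coefficient-*averaged* log
  power at the 20 lowest non-DC bins (≈ 0.2–3.9 Hz). A per-coefficient
  alternative (20 bins × 13 coefficients) was considered and rejected:
  it multiplies dimensionality 13-fold with no fixed-length benefit, and
  the 0.2–4 Hz band is where syllable- and pause-scale information
  lives regardless of coefficient.

The spectrum discards phase, so features are invariant to circular time
shifts; scaling the MFCCs by $c$ shifts non-floored bins by exactly
$2\log c$. Both properties, and agreement with a brute-force
$O(N^2)$ DFT to $10^{-9}$ on short inputs, are enforced in the test
suite.

## Task scoring

The published description fixes the question and the 0–4 range but not
the rubric. The package scores one point per element — year, month, day
of month, day of week — the time-orientation item of the HDS-R lineage
of screening scales, which matches the 0–4 range exactly. Matching is
exact (no ±1-day tolerance; none is published), case-folded, and
tolerant of numeral words and ordinals via JSON rule sets (English and
Japanese shipped; Japanese uses 年/月/日/曜日 marker extraction since
CJK text has no word boundaries). An element found with a wrong value is
`incorrect`; an element not found at all is `absent`; both score zero.
The reference date is an explicit argument, never the wall clock, so
scoring is reproducible. Cloud speech-to-text is out of scope: a
transcriber interface takes its place, with a mock backend and a
sidecar-file backend shipped.

## Classifier

Gradient boosting (via xgboost) over the fixed-order 22-vector
(age, score, ms_01..ms_20). Hyperparameter defaults — 300 trees, depth
3, learning rate 0.05, no subsampling — are conservative
small-tabular-data choices; all are exposed through
`screener_params()`. Training is single-threaded and seeded, so fits
and predictions are bit-reproducible. Dementia is the positive class
everywhere (sensitivity is defined on the dementia group), the decision
threshold is 0.5 with the ≥ convention, and ages outside [20, 100) are
excluded as in the study population. No trained weights are published
for the clinical product, so the package trains on synthetic cohorts
only — it makes no claim to reproduce real-data accuracy, and the
evaluation layer is where the published numbers are reproduced.

## Evaluation layer

Metrics are kept as explicit fractions (numerator, denominator, percent
at one decimal). Percent formatting rounds half *up*, matching the
published table style; base `round()` would turn .X5 ties to even.
Zero-denominator strata report `n/a` rather than erroring, so empty
strata survive stratified reports.

The exact tests are conditional on both margins and two-sided by the
probability-mass rule (sum of probabilities of tables no more probable
than the observed one, with a $10^{-7}$ relative tie slack) — the
convention of R's `fisher.test`, which is used in the test suite as an
independent cross-check but never as the implementation. The 2×2 test
sums hypergeometric probabilities; the r×c test fully enumerates tables
with the observed margins under the multivariate hypergeometric
distribution. For the published 3×2 facility tables the enumeration is
a few hundred tables; a configurable budget guards against larger
tables, with a seeded Monte Carlo fallback (Patefield sampling via
`r2dtable`). Which 2×2 table produced the published "p<0.001" values is
not printed; the package tests the diagnosis-vs-prediction association
table (total and per facility), the standard reading of "evaluating the
classification accuracy". Both published facility-heterogeneity
p-values (0.015 accuracy, 0.010 sensitivity) are reproduced by the
enumeration at printed precision, so no ambiguity remains about that
construction. Age stratification uses decade bins [20,30) … [90,100),
per diagnosis group.

## Synthetic cohorts

The generator emulates the three-clinic study population:

* **Demographics**: stratum sizes exactly as published (489 dementia /
  1097 cognitively normal across facilities A–C) and truncated-normal
  ages per stratum with the published mean ± SD. The real age
  distribution is skewed (many 70s–80s); skewness is *not* modeled.
* **Orientation behavior**: each element is answered wrongly with
  per-class probability 0.45 (dementia) vs 0.05 (normal), giving mean
  scores ≈ 2.2 vs 3.8. Transcripts are generated from the reference
  date with those flips, so scoring and audio stay mutually consistent.
* **Audio**: syllable-like amplitude-modulated harmonic bursts at 3.5 Hz
  (dementia) vs 5.5 Hz (normal) syllable rate with pause fractions
  0.40 vs 0.20, 3 s per response, light per-speaker rate jitter. The
  envelope is periodic at the syllable rate, so the modulation spectrum
  peaks there — the mechanism the acoustic features are designed to
  detect. The reference date (2022-06-15) falls inside the study's
  collection window.

What passing end-to-end tests show: the pipeline recovers class
structure that is genuinely present in the modulation band and the task
score (held-out accuracy ≥ 0.90 at 200 per class), and recovers *no*
structure under a zero-effect null (accuracy 0.5 ± 0.05 over 20 seeds
at 100 per class — the leakage check). What they do not show: anything
about real dementia speech, which differs from the synthetic bursts in
essentially every linguistic and phonetic respect. The fixture
reproducing the published per-facility confusion counts is exact in its
*counts*; which individuals within a stratum are misclassified is
arbitrary, as only counts are published.

Problem sizes used by the validation suite — 400-record separable
cohorts, 20 × 200-record null cohorts, 3-second utterances — were chosen
as the smallest scales at which the acceptance properties are stable.

## Known limitations

* The orientation rubric (4 × 1 point, exact match) is an informed
  assumption; the deployed product's rubric is unpublished.
* English transcripts identify the day of month from bare numerals,
  which can collide with a spoken (wrong) year fragment in free text;
  the bundled generator always produces unambiguous transcripts.
* The MFCC parameterization of the deployed product is unpublished;
  defaults here are field-conventional.
* Specificity heterogeneity across facilities (p = 0.058 on the
  published counts) is computed and reported but was not printed in the
  original analysis; nothing is asserted about it.
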