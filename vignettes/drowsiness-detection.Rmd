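---
title: "Person-adaptive spectral drowsiness detection: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-adaptive spectral drowsiness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drowseeg)
```

## The detection problem

At the transition from relaxed wakefulness (stage W) to stage-1 sleep —
the physiological proxy for drowsiness — the EEG spectrum reorganizes in a
stereotyped way: power in the alpha band (8–12 Hz) drops sharply while
power around 3–4 Hz rises. The alpha peak, however, does not sit at the
same frequency in every person; its position, the Individual Alpha
Frequency (IAF), varies across individuals (notably with age). A detector
built on fixed band centers therefore mixes one person's alpha with
another's theta. `drowseeg` instead anchors everything on each person's
own spectrum and trains a separate classifier per subject — the models are
deliberately person-dependent, trading transferability for accuracy.

## The processing model

Each recording is band-pass filtered at 0.5–50 Hz with a second-order
Butterworth filter and cut into 30 s epochs on the sleep-scoring grid
(epoch *i* covers samples `[i*N, (i+1)*N)`, 0-based and half-open
everywhere in the package). Only W and S1 epochs are kept; W maps to
`alert`, S1 to `drowsy`, and drowsy is the positive class throughout.

**Filtering mode.** The filter order and cut-offs fix the magnitude
response but not how the filter is applied. We default to zero-phase
(forward–backward) application: offline analysis should not let group
delay shift spectral content across epoch boundaries. This squares the
magnitude response — the effective attenuation order doubles — which is
documented on `bandpass()`; a causal single-pass mode is retained for
parity with streaming implementations.

**Spectral estimate.** One symmetric Hanning window and one whole-epoch
FFT per segment, power `PSD(k) = |X(k)|^2 / N`. Three deliberate
numerical choices:

* *No window power-loss compensation.* All downstream features are
  single-bin lookups or band ratios within this one convention, so the
  window constant cancels; absolute PSD values are not comparable with
  compensated estimators (e.g. Welch).
* *No zero-padding.* Padding would move the bin frequencies and thus
  change which bin a physical frequency maps to. At 250 Hz and 30 s the
  bin width is 1/30 Hz.
* *Nearest-bin lookup with half-way ties rounded up.* `P(f)` reads a
  single bin, so the frequency-to-bin rule must be deterministic;
  `bin_of()` implements `round(f*N/fs)` with `.5` up (base `round()`
  rounds to even, which would make tie behavior value-dependent).

**Features.** Per epoch: power at the IAF (the 8–12 Hz argmax, ties to
the lowest frequency so a flat spectrum has a defined answer), power at
the theta anchor TF = IAF − 4 Hz, power at 3 Hz and at 4 Hz, and the
ratio of mean 3–4 Hz power to mean 8–12 Hz power (band edges inclusive
at both ends). A zero alpha denominator — possible only for degenerate
inputs such as an all-zero epoch — raises an explicit
"degenerate alpha band" error rather than returning infinity.

**IAF anchoring modes.** The IAF can be located in each epoch's own
spectrum (`per_epoch`, the default) or once per subject in the mean PSD
over that subject's wake epochs (`subject_mean`). The wake restriction
exists because the alpha peak is a wake phenomenon: averaging attenuated
S1 spectra into the reference blurs the peak. Per-epoch anchoring adapts
to within-night drift but lets the anchor wander under heavy noise;
subject-mean anchoring is the stabler choice on noisy data. Under
per-epoch anchoring the subject-level anchor reported alongside the
feature table is the median per-epoch wake IAF, snapped to an observed
bin value so that TF = IAF − 4 stays exact.

## The classifier

A single-hidden-layer perceptron per subject: 5 inputs, one output score
in (−1, 1) with alert coded −1 and drowsy +1, decision threshold 0 (a
score exactly at the threshold predicts alert — the conservative choice
for an alerting system is debatable, but a fixed rule beats an undefined
one). The fit is delegated to `nnet`; its logistic sigmoid units are an
affine reparametrization of tanh units, so the realized decision-surface
family is the tanh-type network's, and the logistic output *p* is
reported on the (−1, 1) scale as 2*p* − 1. The training contract is
behavioral — accuracy and seed-determinism — not weight-exact, since no
particular optimizer is part of the method.

Features are z-scored before the network, with center and scale learned
from the training rows only and stored inside the model: the raw
features span orders of magnitude (single-bin powers vs. a ratio near 1),
which unscaled gradient training tolerates badly, and learning the
scaling outside the training fold would leak test information.

The hidden-layer size is swept over 5, 10, 15, 20, 25 neurons. The sweep
runs *inside* each training fold (stratified 3-fold internal
cross-validation on the training rows; ties go to the smaller network),
so the outer cross-validation estimate is not biased by model selection.
Three inner folds rather than five keep the full sweep — 10 outer folds
× 5 sizes × (3 inner fits + 1 refit) per subject — cheap enough to run
routinely; on 36-row training sets the selection is insensitive to this
choice because the candidate networks all reach the ceiling on separable
data.

## Evaluation

Stratified 10-fold cross-validation per subject (per-fold class
proportions within one row of the overall proportions). Stratification
is a deviation from a plain random split, adopted because with a few
dozen epochs an unstratified fold can lack a class entirely, leaving TPR
or TNR undefined. Metrics are TPR, TNR and accuracy as percentages, at
full precision, with zero-denominator metrics flagged by name rather
than averaged away. Because fold-averaged and pooled-count metrics can
differ when folds are uneven, `kfold()` reports both, labeled. Cohort
summaries are unweighted means of per-subject values — each person
counts equally regardless of epoch count, the convention used in
per-subject performance tables for person-dependent classifiers.
With equal class counts, accuracy = (TPR + TNR)/2 exactly; the test
suite checks this identity on random confusion tables.

## What the synthetic cohort does and does not emulate

The generator is the package's test bed, not a sleep simulator. Each
subject is three tones over noise: an alpha sinusoid at a per-subject
IAF, 3 Hz and 4 Hz sinusoids, and 1/f-shaped Gaussian background
(white noise shaped by a 1/sqrt(f) spectral envelope, DC zeroed,
normalized to unit variance — simple and exactly seedable). In S1 the
alpha amplitude is multiplied by 0.3 and the slow-tone amplitude
tripled, realizing the band-power transition the method assumes. Phases
are redrawn per epoch so epochs are exchangeable within a state.

Default study conditions: 10 subjects with IAFs recycled over the grid
8.5–11.5 Hz in 0.5 Hz steps (all grid points are exact bin centers at
1/30 Hz resolution), 20 wake + 20 S1 epochs per subject, 250 Hz, 30 s
epochs. The background level is set by `calibrate_noise_amp()`, which
measures the alpha-band variance of unit noise spectrally and scales it
so alpha-band noise power is 10% of the wake alpha tone power — "moderate"
noise in the sense that the wake alpha peak remains the band maximum in
essentially every epoch.

What this deliberately omits: sleep microstructure (spindles,
K-complexes), ocular and muscle artifacts, alpha peaks that drift or
split, non-stationary noise, and class imbalance. Passing tests on this
cohort therefore demonstrate that the pipeline is implemented correctly
and recovers its own generative parameters — near-ceiling accuracy here
says nothing about accuracy on real polysomnography, where published
per-subject accuracies for this family of methods sit around 85–100%.
Real recordings can be supplied as CSV or EDF with text hypnograms; the
evaluation path is identical.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run the default cohort
(10 subjects × 40 epochs, 300 000 samples per subject), the spectral
oracle on 50 epochs of length 16–256 against a brute-force DFT, the
noiseless and 10%-noise recovery experiments (200 wake epochs each), and
the full cross-validation sweep over three cohort seeds — sizes chosen so
a complete run stays in the tens of seconds while every stage is
exercised end to end.

## Known limitations

* Person-dependent by design: no cross-subject transfer, no
  leave-one-subject-out evaluation.
* Single channel, no artifact rejection or re-referencing; heavily
  contaminated epochs will corrupt both anchors and features.
* The 8–12 Hz alpha search window is fixed; subjects with an alpha peak
  at the window edge are clamped to it, and the ratio denominator uses
  the fixed band rather than an IAF-centered one.
* The EDF layer covers plain continuous EDF (16-bit, linear scaling)
  only — no EDF+ annotations; hypnograms travel as separate text files.
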