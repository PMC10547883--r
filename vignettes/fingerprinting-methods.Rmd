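---
title: "Neural fingerprinting with random convolutional kernel transforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural fingerprinting with random convolutional kernel transforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rocketfp)
```

## The problem

Neural fingerprinting asks whether a short window of brain activity can be
assigned to the individual it was recorded from. In MEG/EEG work this is
usually done with second-order summaries (connectomes, spectral features);
the approach implemented here instead classifies the multivariate time
series directly. Each subject-session recording is a `regions x samples`
matrix of source-space label time courses; windows of a second or two
("trials") are transformed into pooled random-convolution features and a
linear classifier assigns each test trial to one subject in the cohort.

## The transforms

**Random kernels.** A random convolutional kernel is described by a length
$l_k \in \{7, 9, 11\}$, a dilation $d$, mean-centred Gaussian weights $w$, a
bias $b \sim U(-1, 1)$, a padding flag, and — for multivariate input — a
channel subset. The convolution is the dilated sliding dot product

$$C_t = \sum_{c} \sum_{j=0}^{l_k - 1} X[c,\, t + j d]\, w[c, j] + b,$$

and each kernel contributes two pooled features per trial: the global
maximum of $C$ and the proportion of positive values
$\mathrm{ppv} = \tfrac{1}{n} \sum_i [C_i > 0]$ (strict inequality; zeros are
not positive). Dilations are drawn on an exponential scale,
$d = \lfloor 2^x \rfloor$ with $x \sim U(0, A)$ and
$A = \log_2\!\big((l_\mathrm{input} - 1)/(l_k - 1)\big)$, so the dilated
receptive field always fits the trial and the kernel population spans
time scales — large dilations respond to slow rhythms, small ones to fast
structure. The printed form of this scale in the source literature is
typographically ambiguous (a ratio of reciprocals); the conventional
reading adopted here is the one that makes every sampled dilation
admissible. Padding, when on, adds $(l_k - 1)d/2$ implicit zeros per side —
the dilation-aware generalization of the undilated half-width — so padded
outputs keep the input length. The channel subset rule is not fixed by the
method's description; this package draws the subset size as
$\lfloor 2^u \rfloor$, $u \sim U(0, \log_2(n_\mathrm{ch} + 1))$, which
favours small subsets while allowing occasional large ones, then samples
that many distinct channels uniformly. The single bias is added once per
output sample, not once per channel.

**Fixed kernels.** The faster variant replaces random weights with the 84
length-9 patterns over $\{-1, 2\}$ that contain exactly three 2s (so every
kernel sums to zero), assigns each pattern up to 32 geometrically spaced
dilations whose 9-tap receptive field fits the trial, and spreads the
requested feature budget as evenly as possible over (pattern, dilation)
combinations. Biases are not random: each feature's bias is a quantile of
its combination's convolution output on one uniformly drawn training
trial, with quantile levels following a golden-ratio low-discrepancy
sequence over $(0,1)$ so thresholds tile the output distribution evenly.
Because the literature defers the bias details to its reference
implementation, any deterministic, documented quantile spread is
admissible; this one was chosen for its even coverage with a single
training pass. Feature slots alternate globally between a kernel and its
sign-inverted twin. Inverted features are *not* computed by a second
convolution: since the proportion of negative values satisfies
$\mathrm{pnv} = 1 - \mathrm{ppv}$ on tie-free data, the inverted feature at
threshold $b$ is evaluated as $\mathrm{mean}(C < -b)$ from the same output.
This form (rather than literally $1 - \mathrm{ppv}$) also behaves correctly
under ties: on an all-zero training signal every bias is 0 and every
feature — regular or inverted — is exactly 0. "Fixed padding" is read as a
deterministic alternation (padding on for every second combination), one
of the two readings the description admits; a coin flip would re-introduce
randomness the variant exists to remove.

The swept "number of kernels" maps to the fixed-kernel variant's feature
budget; the budget is spread evenly, so no rounding to a multiple of 84 is
required.

## Classifier and metrics

Features are standardized with training statistics only, and a one-vs-all
ridge regression on $\pm 1$ indicator targets provides per-class scores.
The regularization strength is selected from 10 log-spaced values on
$[10^{-3}, 10^3]$ (the method names no grid; this one brackets the useful
range at these feature scales) by stratified 5-fold cross-validation of
the squared target error, falling back to the closed-form generalized
leave-one-out error when any class has fewer members than the fold count.
All fits run through a single SVD, so the full grid costs one
decomposition; a closed-form direct solve serves as the oracle in tests.
Prediction takes the arg-max score with ties broken toward the earlier
class in sorted subject order, for deterministic behaviour.

Per class, precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$ and
$F_1 = 2PR/(P+R)$; macro averages weight classes equally. A class never
predicted (and without true positives) receives precision and $F_1$ of 0 —
the convention that penalizes ignored classes in the macro mean. Balanced
trial sampling makes test sets class-balanced, so accuracy equals macro
recall there.

## Experiment designs

* **Session pair** (`fingerprint_sessions()`): z-score each region of the
  continuous recording (zero-variance regions are centred to zero with a
  warning), cut consecutive non-overlapping trials, sample a fixed number
  per subject for balance, fit the transform and classifier on the
  training session only, and score the test session. Each recording is
  z-scored on its own continuous course; no statistics cross sessions.
* **Leave-one-subject-out** (`loom_evaluate()`): each subject is removed
  from both sets once; the remaining cohort is evaluated as above. The
  within-run aggregate is the metrics of that single evaluation (the
  source protocol does not define the within-run average; this is the
  simplest faithful reading), and the summary is the mean and standard
  deviation across left-out runs.
* **Sweeps** (`parameter_sweep()`): one axis (feature budget, trials per
  subject, trial duration) varies while the others stay at the reference
  operating point — 3,500 kernels, 15 trials, 1.5 s — with fresh trial
  selections and kernel seeds per repeat; mean/min/max accuracy per value.
* **Cross-over** (`crossover_experiment()`): all 9 ordered pairs of
  {rs1, rs2, empty}. Same-session cells split the continuous recording in
  half and draw training trials from the first half, test trials from the
  second (10 per subject in the reference design), so the sets never share
  samples. Comparing rest-rest with rest-empty cells isolates how much
  day-specific sensor-room noise could drive identification.

One master seed expands into per-stage streams (`derive_seed()`, a
multiplicative hash kept below $2^{31}$), so kernel initialization and
trial selection are independently reproducible.

## The synthetic cohort

Real multi-session MEG source data cannot ship with a package, so the
generator emulates the statistical structure the analysis relies on:

* each subject owns a stable signature — 6 oscillators with frequencies
  uniform on 1–40 Hz, random amplitudes, a `regions x oscillators`
  Gaussian mixing matrix — persisting across resting sessions; oscillator
  phases are redrawn per session so waveforms differ while spectra match.
  Dilation sensitivity to frequency content is exactly what the
  fixed-kernel transform can exploit, which makes spectral signatures the
  natural minimal model of subject identity here;
* every session adds fresh per-region $1/f$ noise (spectral shaping of
  white noise, unit variance, exponent 1 by default), with the oscillatory
  part rescaled so signature power is `snr` times noise power
  (default 3, a clearly identifiable regime; `snr = 0` gives the null
  cohort used for chance-level checks);
* a fraction of the signature (default 0.1) is redrawn between rs1 and
  rs2, modelling day-to-day state drift;
* empty-room sessions are noise plus a day component with its own
  oscillator mixture, scaled to `empty_day_structure` (default 1) times
  noise power and *shared identically across subjects*, so empties carry
  day structure but no subject information. Whether real empty-room
  projections share or split such structure per subject is ambiguous in
  the source protocol; the amplitude parameter lets either regime be
  approximated, and the default is the subject-uninformative one.

Defaults: 25 subjects, 68 regions, 250 Hz, 40 s per session. The sampling
rate is far below raw MEG rates; it keeps desk-scale memory and runtime
while preserving the 1–40 Hz band the signatures occupy. What passing
tests on this cohort shows is that the pipeline recovers planted,
spectrally expressed identity under realistic noise — not that it would
reach any particular accuracy on real recordings, which carry artifacts,
nonstationarity and far richer cross-subject similarity.

## Numerical choices and degenerate inputs

* Convolution is exact (no FFT); the compiled path for the fixed kernels
  uses the two-valued decomposition $C = 3\sum_{j \in P} y - S$ with a
  sliding 9-tap sum per dilation residue class, and equals the literal
  per-placement formula to $10^{-9}$ on randomized oracles in the tests.
* ppv uses strict `>`; the inverted slots use strict `<`.
* Zero-variance features get scale 1 in standardization; zero-variance
  regions z-score to 0 with a warning.
* Trailing samples shorter than one trial are dropped; odd-length half
  splits give the extra sample to the second half.
* Errors of class `rocketfp_invalid_input` name the offending subject or
  field where applicable.

## Problem sizes used in the shipped checks

The package's own validation runs the default 25-subject cohort with the
840-feature operating point: one rs1→rs2 evaluation (15 trials × 1.5 s),
sweeps over {100, 500, 2000} features, {0.2, 0.5, 1.5} s and {3, 8, 15}
trials at 5 repeats, and the 9-cell cross-over at 10 trials per subject
with 3 repeats; `scripts/acceptance.R` re-runs the same designs at 3
repeats and adds a leave-one-out summary on an 8-subject subcohort. These
sizes are the package's reference desk-scale conditions; the mean/min/max
tables they produce mirror the structure of the full-scale results they
emulate.

## Known limitations

* The generator targets statistical, not biophysical, fidelity: no
  forward model, sensor noise covariance, artifacts or head movement.
* Only ridge classification is provided; the stochastic-gradient logistic
  variant recommended for very large cohorts is out of scope.
* Significance testing between design orderings is not implemented.
* Real MEG ingestion (sensor formats, preprocessing, source localization)
  is out of scope; recordings enter as `regions x samples` matrices.
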