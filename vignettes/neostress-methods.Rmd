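---
title: "Methods: bradycardia-based stress classification in neonatal multichannel physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bradycardia-based stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Preterm infants in intensive care experience transient heart-rate drops
(bradycardias) that frequently co-occur with drops in oxygen saturation.
There is clinical evidence that accumulated procedural pain — "stress load" —
changes how an infant reacts to such hypoxic events: deeper desaturations,
more regular (discontinuous) EEG, and stronger coupling between cortical and
cardiovascular rhythms.  `neostress` implements an event-based classifier of
that contrast: it detects bradycardia-plus-desaturation events in
multichannel recordings (8 EEG channels at 256 Hz, an RR tachogram, SpO2 at
1 Hz), extracts a large univariate and network-physiology feature set from
the minutes surrounding each event, and asks whether the event belongs to a
stressed patient (any non-zero pain score the day before the recording),
evaluated with leave-one-patient-out (LOPO) cross-validation per monitoring
group (around day 5, around 34 weeks post-menstrual age, and a pre-discharge
polysomnography).

Because comparable clinical recordings are not freely available, the package
ships a synthetic-cohort generator whose effect sizes are independently
controllable, so that every pipeline stage — including the end-to-end
classifier — is testable against known ground truth.

## Event detection

* **Bradycardia**: a maximal run of beats whose RR interval exceeds
  1.5 × the mean RR of the *entire* tachogram, with summed RR duration of at
  least 4 s.  Runs separated by fewer than 5 sub-threshold beats are merged.
  The event peak is the maximal RR interval (earliest on ties).
* **"Return to stationarity"** closes the event: the first beat after the
  peak whose RR falls to 1.1 × mean RR, sustained for 5 beats.  A bare
  threshold re-crossing would leave slow recovery tails inside the "post"
  epoch; the sustained criterion is our operationalization of an otherwise
  informally described endpoint, and both constants are configuration
  entries.
* **Desaturation**: the local baseline is the running median of the
  preceding 60 s; an event is a region below baseline − threshold
  (3, 5 or 10 %), extended outward to the re-crossing of
  baseline − threshold/2; its depth is baseline-at-onset minus nadir.  The
  60-s trailing median is a documented stand-in for the published
  SpO2 detector this stage is modelled on.
* **Pairing**: a desaturation joins a bradycardia when their intervals
  intersect `[onset − 30 s, offset + 60 s]`; nearest nadir wins ties; each
  desaturation is used at most once; unpaired bradycardias are dropped.
* **Window and epochs**: each hypoxic event owns a 6-min window centred on
  the bradycardia peak (truncated and flagged at record edges), partitioned
  half-open into *pre* (window start → bradycardia onset), *during*
  (onset → offset) and *post* (offset → window end).  SpO2-specific epochs
  use the desaturation's own onset/offset.  EEG is band-pass filtered
  1–20 Hz (zero-phase 4th-order Butterworth) before any feature extraction.

## Feature families

**Cardiovascular and oximetry (per event).**  Beat-domain mean and SD of RR
per epoch; mean and SD of SpO2 over the desaturation-anchored epochs.
Wavelet band powers of the 8-Hz-resampled RR series (analytic Morlet,
ω₀ = 6, 12 voices/octave) in HF = (0.2–4] Hz and LF = (0.08–0.2] Hz, with
per-epoch mean and SD of HF, LF, HF/(LF+HF) and LF/HF (cone-of-influence
samples excluded).  Poincaré descriptors (lag at the first autocorrelation
zero; SD1/SD2 as singular values of the centred two-column embedding scaled
by 1/√(n−1); uncentred centroids) once per event window.  Phase-rectified
signal averaging (PRSA) slopes: anchors where the mean of the following T
seconds is below (SpO2, "down") or above (RR, "up" — an RR rise is a
deceleration) the preceding T seconds, for
T ∈ {1, 5, 10, 20, 50, 100} s; 120-s fragments are averaged and summarized
by the overall least-squares slope and the slope over `[anchor, anchor+T]`.
PRSA and Poincaré use the whole 6-min window: a 120-s fragment cannot fit
inside short epochs.

**EEG (per channel).**  Mean and SD of the filtered signal and of its
delta-band (0.5–4] Hz instantaneous power per epoch.  The delta-power CWT
runs on 4×-decimated EEG (64 Hz); the band tops out at 4 Hz, so decimation
is transparent in-band.  Wavelet-leader multifractal log-cumulants c₁
(dominant Hurst exponent, a regularity measure) and c₂ (multifractality
width) of the raw channel and of its delta-power envelope (at 8 Hz), for the
pre and post epochs only — the during epoch is too short for fractal
estimation.  The estimator uses a Daubechies-3 pyramid, leaders as suprema
of absolute coefficients over the 3-neighbourhood at all finer scales,
and weighted regression of the log-leader mean/variance on j·ln 2 over
octaves 3 … ⌊log₂ n⌋ − 3 with weights n_j.  Signals are demeaned and
integrated (cumulative sum) first, which shifts regularity exponents by +1
and places increment-type signals (fGn-like EEG backgrounds) in the range
the leader formalism requires; for fGn the estimated c₁ then equals the
generator's Hurst exponent, which is the calibration the tests check.

**Network physiology (per event).**  Ten node series at 8 Hz over the event
window: the 8 delta-power envelopes, the resampled RR series and SpO2.  For
every pair, the complex wavelet coherence
C = S(WₓW_y\*) / √(S|Wₓ|² S|W_y|²) is computed on an analytic-Morlet scale
grid covering the group's coupling band (VLF = (0.033–0.08] Hz for the
5-days group, LF for the others) at 6 voices/octave.  The smoothing S is a
Gaussian-shaped kernel of standard deviation equal to the scale in time
(realized as a three-pass boxcar cascade, implemented in C++) and a 3-voice
boxcar across scales — without smoothing, coherence is identically 1.  The
coupling statistic is the time-mean (outside the cone of influence) of the
maximum over in-band scales of |Im C|; the imaginary part ignores
instantaneous co-variation, so only lagged coupling counts.  Each pair's
statistic must exceed the same statistic of all 19 AAFT surrogates of its
first node (α = 1/20); tested once per pair per event (per-sample testing
has no resolution at 19 surrogates).  Non-significant pairs are masked to
zero.  On the significant graph, charts of path length, efficiency,
clustering (Onnela weighted coefficient), eccentricity and the number of
superfluous connections are evaluated on a 1-Hz grid (the smoothing widths
exceed several seconds, so a finer chart grid carries no information), per
partition (EEG–EEG, EEG–SpO2, EEG–RR, all pairs), and aggregated as
mean/SD per epoch.  Distances are inverse weights; shortest paths by
Floyd–Warshall.  The redundancy optimum n_sup maximizes H + E over the
number of smallest weights removed, where H is the entropy of the remaining
weights renormalized to a distribution (entropy is otherwise ill-defined
for weights not summing to one) and E the squared deviation from the
original weights; a configuration switch offers H − E because maximizing
deviation is arguably counter-intuitive for a resilience measure — both
variants pass the same argmax-stability tests.

## Classifier

One feature row per hypoxic event; power features are natural-log
transformed.  Inside every LOPO fold (never on the full table): features
significantly Pearson-correlated with post-menstrual age (p < 0.05 on
training rows) are replaced by residuals of a training-fitted linear model;
F-scores (Chen–Lin class-separation ratio) rank the features; a greedy pass
drops any feature correlated above 0.9 with an already retained one and
keeps at most 3 × ⌊n_train/10⌋ features; missing values are imputed with
training medians.  The classifier is a subspace ensemble of
pooled-covariance linear discriminants: each learner sees a stratified
bootstrap resample and a uniformly random feature subset of size
⌊n_train/10⌋ (the one-tenth rule); the ensemble score is the mean learner
posterior; the ensemble size is selected from {15, 30, 60} by 10-fold
cross-validation within the training fold.  Degenerate within-class
covariance falls back to shrinkage (γ = 0.1) toward the scaled identity.
Pooled test scores give the AUC (rank statistic) and Cohen's kappa at a
posterior threshold of 0.5 (the operating point is a design choice), per
monitoring group and desaturation threshold.

## The synthetic cohort

`generate_subject()` builds records with exactly the statistical structure
the analysis assumes, and nothing more:

* **Tachogram**: beats are laid down sequentially with instantaneous RR =
  0.42 s × (1 + modulations) × bradycardia profile.  Modulations: a
  coupling-band component (amplitude 1.2 %), an independent LF component
  when the coupling band is VLF (0.8 %), and an HF "breathing" component
  (0.8 %, raised by the HF effect for stressed PSG subjects).
* **Bradycardias**: multiplicative raised-cosine profiles; `duration_s` is
  the full width at half elongation, so a depth-2.0, 8-s event stays above
  the 1.5× criterion for about 8 s.  Depths are drawn from
  U(1.7, 2.5) and durations from U(6, 12) s; events are spread with at
  least one full analysis window between peaks.
* **SpO2**: baseline 96 % plus AR(1) oximeter noise (σ = 0.3 %, ρ = 0.9 —
  slow oximeter dynamics) and raised-cosine desaturations co-timed with the
  bradycardias (±3 s), depth N(8, 2.5²) truncated at 3.5 %, duration
  U(15, 45) s.
* **EEG**: per channel, a fractional Gaussian background (Davies–Harte
  exact simulation, Hurst 0.6 for controls) plus a delta-band carrier whose
  amplitude envelope mixes a shared band-limited process with an
  independent one.  The shared process is the analytic signal of
  band-limited noise in the group's coupling band: its real part drives the
  EEG envelopes, its imaginary part (a 90° phase offset) drives the RR
  coupling component, so the injected coupling is maximal in the imaginary
  coherence the pipeline measures.
* **Stress effects** (all zero ⇒ the stressed flag is inert, by
  construction on the same random-draw path): +4 percentage points of
  desaturation depth, +0.15 EEG Hurst, +0.2 RR-side coupling mixing weight,
  +50 % HF amplitude (PSG only).

What the generator does **not** emulate: realistic EEG/ECG morphology,
artifacts (synthetic EEG is artifact-free, so no ICA stage exists),
sleep states, maturational EEG changes (groups differ only through the
coupling band and metadata), apnea mechanics.  Passing tests therefore show
that the pipeline recovers the *statistical* contrasts it targets, not that
it is robust to the messiness of real NICU data.

## Numerical choices

* Analytic Morlet with ω₀ = 6; scale s = ω₀/(2πf); cone of influence at the
  e-folding time √2·s; FFT padding covers six of the largest scale.
* Band-power grids at 12 voices/octave; the coherence grid at 6
  voices/octave, so the 3-voice scale boxcar smooths over half an octave.
* The three-pass boxcar cascade matches the Gaussian's standard deviation
  (h from sd = √(h(h+1)/3)) and keeps unit DC gain with truncated edge
  windows; identical smoothing is applied to numerator and denominators, so
  self-coherence is exactly 1.
* Half-open `[start, end)` epoch intervals everywhere; an RR interval ends
  at its beat time.
* Ties: earliest maximal RR is the peak; smallest n wins the n_sup argmax;
  AUC uses midranks.
* Degenerate inputs: constant series have no surrogates or ACF zero
  (errors), epochs with fewer than 2 samples yield missing values, fractal
  estimates need 2^10 samples and 3 usable octaves; missing features are
  median-imputed inside training folds only.
* One master seed governs synthesis, surrogates and bagging; per-stream
  seeds are derived with integer mixing kept below 2^31.

## Problem sizes used by the checks

The package's defaults describe hour-long records with a Poisson(8) event
count.  The end-to-end checks (parameter recovery, null behaviour) run on
20 subjects in one monitoring group at the same 8-per-hour event rate: the
effect-recovery arm on 15-min records (~35 events — the stress effects are
large enough that the AUC ≥ 0.8 band passes with a wide margin at any
size), the null arm on half-hour records (~65 events, the larger count
because its bands are the variance-limited ones).  Estimator calibrations
use n = 2^15 samples and 20 replicates; detector equivalence uses 200
random tachograms; the surrogate α-level check uses 200 independent-noise
trials.

One caveat deserves emphasis: the pooled LOPO score of a subject's events
comes from that subject's own fold model, so under the null the pooled AUC
and κ behave like statistics over ~20 subjects rather than ~65 events.
Their sampling spread (sd ≈ 0.12–0.15 for the AUC) is therefore governed by
the subject count, and chance-level bands such as AUC ∈ [0.4, 0.6] are only
loosely resolved by a single 20-subject cohort — replications across master
seeds straddle the band.  The effect-size contrast, by comparison, is far
outside this noise floor.

## Known limitations

* The feature accounting differs from any single printed total: this
  pipeline emits 348 features (means/SDs per epoch, window-level PRSA and
  Poincaré, pre/post fractals, 120 topology aggregates); the registry
  (`feature_registry()`) is the authoritative enumeration.
* The "return to stationarity" rule, the desaturation baseline and the
  pairing tolerances are documented operationalizations of informally
  specified steps; all are configurable.
* EDF input is not supported — CSV bundles are the interchange format.
* LOPO with few subjects per class yields noisy pooled AUC and kappa
  estimates (see the problem-size caveat above); sparse network partitions
  additionally carry subject-level "fingerprints" under the null, which is
  the known pessimistic-bias regime of leave-one-group-out evaluation with
  in-fold feature selection.  Equal-prior, balance-bootstrapped learners
  remove the systematic part of that bias; the subject-count-limited
  variance remains.
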