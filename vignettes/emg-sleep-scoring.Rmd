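---
title: "Sleep/wake scoring from anterior tibialis EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep/wake scoring from anterior tibialis EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsleep)
```

## The problem and the signal

Sleep efficiency — the fraction of a night's 30-s epochs scored as sleep —
is clinically meaningful, but its reference measurement (polysomnography
with expert staging) is expensive. Actigraphy misses quiet wakefulness
because it senses mechanical movement only. The anterior tibialis surface
EMG is an electrical alternative: during wakefulness the muscle shows
elevated tonic tone and bursts, including *isometric* activity while the
subject lies motionless; during sleep the tone falls to a low, stable
level. The tibialis EMG cannot distinguish REM from non-REM sleep (leg
tone does not change systematically at that transition), so this package
estimates the binary sleep/wake sequence only; stages 1–4 and REM are all
"sleep".

## The two estimators

Both estimators are *self-normalizing*: their thresholds are scalar
multiples of statistics of the night being scored, so classifications are
invariant to any positive rescaling of the raw amplitudes (amplifier gain,
electrode impedance). This invariance is tested property-style.

### Time-domain rule

With samples $x_j$ at $f_s$ Hz, the per-second energy and per-epoch
energy are $y_k = \sum_{j=(k-1)f_s+1}^{k f_s} x_j^2$ and
$z_l = \sum_{k=(l-1)30+1}^{30l} y_k$. The adaptive amplitude threshold for
epoch $m$ is

$$T_m = \mathrm{TSF}_1 \cdot \overline{z}_{[m-\mathrm{TSF}_2,\, m+\mathrm{TSF}_2]},$$

a windowed mean of $2\,\mathrm{TSF}_2+1$ epochs (about 25 minutes on each
side at the default $\mathrm{TSF}_2 = 25$), so slow drifts in baseline
tone move the threshold with them. $\mathrm{HEMG}_m$ counts the seconds of
epoch $m$ whose $y_k$ strictly exceeds $T_m$ (an exactly-equal value does
not count, following the sign-function convention $\mathrm{sgn}(0)=0$),
and an epoch is wake iff $\mathrm{HEMG}_m$ strictly exceeds the
whole-night mean of the counts. Both comparisons break ties toward sleep.
The mean-count decision line makes this an offline rule: the whole night
must be available.

Two things about this rule are worth stating plainly. First, $T_m$ is of
the order of $\mathrm{TSF}_1 \times 30$ times the mean *per-second*
energy, so only genuinely large excursions — movement bursts, not mild
tonic elevation — push seconds over it. Second, any activity during sleep
(periodic limb movements) inflates both the threshold *and* the decision
line, which is precisely the mechanism by which the estimator degrades in
the PLMD profile below.

### Frequency-domain rule

Each whole epoch is transformed with a plain periodogram — FFT of the raw
30-s segment, no taper, no detrending, frequency resolution 1/30 Hz — and
the one-sided power is summed over the band informative for surface EMG:
10–75 Hz inclusive, minus the mains interval (55–65 Hz by default,
configurable to 45–55 Hz in 50 Hz regions). Below 10 Hz live movement
artifact and baseline wander; above 75 Hz mostly noise; the exclusion
edges are themselves excluded so a tone at exactly 55 or 65 Hz is
rejected. With no masking the summation satisfies Parseval exactly
(verified to 1e-6 relative tolerance in the tests), which fixes the
scaling convention. The spectral threshold is
$\mathrm{TSF}_1\,\mathrm{mean}(tp) + \mathrm{TSF}_2\,\mathrm{sd}(tp)$
with the *sample* standard deviation (divisor $N-1$; the same convention
reproduces the published summary-table arithmetic), computed once from
the scored night's own series. The sampling rate must exceed 150 Hz so
the retained band lies below Nyquist; rates at or below that are a
configuration error rather than a silently clipped band. An optional Hann
taper (`fda.window` equivalent: `window = "hann"`) is provided for
leakage-heavy spectra; its power scaling is immaterial because the
threshold is self-normalizing.

### Open choices resolved

* **Bilateral combination.** Whether the validation study summed bilateral
  energies or used one leg is not documented. Energy is additive, so the
  default combines channels by element-wise summation of $y$, $z$ and
  $tp$ before thresholding, keeping a single threshold pipeline. The
  alternative — classify each channel and call wake if either does — is
  available as `combine = "or"`.
* **Whole-night statistics.** The FDA mean and SD (and the TDA mean
  count) are taken from the recording being scored, i.e. the threshold
  adapts to the subject's own night. This is the reading most consistent
  with a subject-adaptive threshold; training nights only choose the
  multipliers.
* **F-measure.** The statistic is implemented as the harmonic mean of PPV
  and sensitivity (precision and recall). The alternative
  sensitivity–specificity harmonic mean is available as
  `f_variant = "sens_spec"`, but every published per-subject F value this
  package reproduces matches the precision–recall form.
* **Unscored epochs.** Movement-time or unscorable epochs become
  `EXCLUDED` and are dropped pairwise from all agreement counts; the
  handling is this package's convention.
* **Single-class references.** Against an all-sleep (or all-wake)
  reference, chance-corrected agreement is not meaningful: kappa and the
  undefined ratios are reported as `NA` with a warning, and calibration
  drops such recordings from the training mean.

## Calibration

The threshold-selection factors are chosen by exhaustive grid search
maximizing mean Cohen's kappa across training recordings, inside a
leave-one-subject-out loop: each fold calibrates on the other subjects
and scores the held-out night. Kappa, not accuracy, is the objective
because sleep prevalence near 97% makes accuracy insensitive to wake
detection. The default grids,
$\mathrm{TSF}_{TDA1} \in \{1,\dots,10\}$,
$\mathrm{TSF}_{TDA2} \in \{5,10,\dots,50\}$,
$\mathrm{TSF}_{FDA1} \in \{0,0.25,\dots,2\}$,
$\mathrm{TSF}_{FDA2} \in \{0.5,1,\dots,5\}$,
bracket the published exemplar settings (4, 25) and (0.5, 3.5) by roughly
an order of magnitude and contain both exactly. Ties break toward smaller
$\mathrm{TSF}_1$, then smaller $\mathrm{TSF}_2$ — the least aggressive
thresholds among equals — making selection deterministic.

## The synthetic generator

`simulate_cohort()` exists so that every operation in the package is
testable end to end without clinical data. Its defaults emulate the
validation conditions this package models: ~8-hour nights (960 epochs) at
250 Hz, sleep efficiency near 97.5%, and the amplitude phenomenology of
tibialis EMG.

* **Ground truth.** A two-state Markov chain over epochs; the wake→sleep
  probability is the reciprocal of the mean wake-bout length (default 2
  epochs), and the sleep→wake probability is solved from the target
  stationary sleep efficiency. Infeasible combinations error up front.
  Stage labels within sleep (light sleep ≈65%, slow-wave ≈12%, REM ≈23%)
  come from a persistent chain; they matter only to the format and
  binarization code, as the estimators see sleep/wake alone.
* **Signal.** Band-limited (10–75 Hz) Gaussian noise whose SD follows the
  state: tonic sleep 1 a.u., tonic wake 3 a.u. (elevated tone and
  isometric activity). Wake epochs receive Poisson-placed movement bursts
  (default 6/min, 0.5–3 s) at 10× the wake tone — surface-EMG movement
  bursts dwarf the sleeping noise floor, and energies of this order are
  required for any second to clear a threshold that sits at
  $\mathrm{TSF}_1 \times 30$ times the mean per-second energy. The PLMD
  profile adds periodic burst trains in sleep (25 s spacing, 2 s width,
  standard PLMS definition ranges) at 20× the sleep tone: genuine
  movements, somewhat weaker than gross wake movements but overlapping
  them enough that no threshold separates the two — reproducing the
  wake overestimation reported for PLMD patients. The OSA profile keeps
  the normal signal model (apnea does not alter tibialis EMG) with more
  fragmented nights. Burst envelopes are shared between the two channels
  (movements show on both legs); `channel_correlation` (default 0.3)
  sets the shared-variance fraction of the tonic noise; an optional
  60 Hz sinusoid models mains pickup and must not leak through the
  spectral mask (tested at the 1% level).
* **What it does not model.** No motor-unit action potentials, no ECG
  crosstalk, no electrode artifacts or detachment, no real PLM morphology
  or inter-night variability structure. Passing the synthetic-recovery
  tests therefore shows the pipeline is correct and the method behaves as
  designed under its own assumptions — not that clinical kappa values
  would be as high; on real nights the published figures (kappa ≈ 0.64 /
  0.67 for the two estimators in normal sleepers) are the realistic
  anchor.

## Numerical conventions and degenerate inputs

Window truncation at the night's ends divides by the number of epochs
actually present, so edge thresholds remain averages of observed
energies and every epoch is scored. A trailing partial epoch is dropped
with a warning; a recording/hypnogram length mismatch of one epoch is
truncated with a warning, larger mismatches are errors. EDF amplitudes
are used as stored physical values without rescaling (the estimators are
scale-invariant anyway); the writer quantizes onto the format's 16-bit
grid against the header value it actually writes, bounding round-trip
error by one digital step. CSV signals are written at full precision
(`%.17g`), making text round-trips exact. All-constant inputs classify
as all-sleep (nothing strictly exceeds its own mean); empty signals,
single-epoch FDA series and all-zero amplitude normalization are errors
with specific messages.

## Problem sizes used in the test suite

The packaged tests run the full design at reduced but representative
sizes, chosen so the suite exercises every code path in minutes: oracle
equivalence on 200 random nights of up to 20 epochs at 10 Hz against
loop-transcription oracles; Parseval and scale invariance on 100 random
cases each; synthetic recovery on two 6-subject cohorts of full 960-epoch
nights at 250 Hz (normal and PLMD), where both cross-validated estimators
are required to reach mean kappa ≥ 0.8 and sensitivity ≥ 0.95 and the
PLMD profile must cost at least 0.1 specificity; and 2000 null
simulations checking the state-amplitude rank test holds its nominal 5%
level within [0.03, 0.07]. The same full-night computation backs
`scripts/acceptance.R`.

## Limitations

The estimators are offline (whole-night statistics), binary (no stage
scoring without EEG/chin EMG), and assume integer samples-per-second with
no resampling support. For PLMD patients the method systematically
overestimates wake — for that population, whole-night tibialis EMG is
better used for PLM detection than for sleep/wake estimation.
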