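---
title: "Quantifying cortical ON/OFF dynamics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical ON/OFF dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsync)
```

## The problem

During NREM sleep, cortical populations alternate between ON periods of
sustained firing and OFF periods of near-total silence, every few hundred
milliseconds. The field potential expresses each OFF period as a slow wave,
and the density and synchrony of OFF periods index sleep pressure. `offsync`
implements the full analysis chain for multichannel cortical recordings of
this phenomenon: multi-unit (MUA) spike detection from wideband traces,
single-channel and population ON/OFF segmentation, slow-wave-activity (SWA)
quantification, OFF-locked waveform metrics, spike-time tiling coefficient
(STTC) synchrony, condition extraction around sleep deprivation, stimulation
protocol generation, and video-pose actigraphy — together with a synthetic
session generator that provides ground truth for every stage.

## The detection model

**Single-channel segmentation.** An ON period is a run of spikes whose
inter-spike intervals are all below 50 ms, timestamped first spike to last.
A candidate OFF period is an inter-run gap of at least 50 ms. A candidate is
accepted when at least one adjacent ON run lasts at least 30 ms: the rule
exists to forbid an "OFF period" bracketed by two single-spike runs, and the
one-sided reading implements exactly that prohibition. The stricter
two-sided reading is available (`off_params(flank_rule = "both")`). Silence
touching the recording edges is never an OFF period in this mode, because
no flanking ON run exists there.

**Population detection.** With the per-channel OFF intervals in hand, the
step function *n(t)* counts channels simultaneously OFF. Maximal intervals
with *n* ≥ 12 (of 16) lasting 50–400 ms are global OFF periods; maximal
intervals with *n* < 12 lasting 50–2000 ms are global ON periods. Intervals
violating their duration bound are returned *unclassified* rather than
truncated or split: the definitions bound the period itself, and fabricating
boundaries inside a longer run would misstate its extent. A consequence
worth knowing: the *duration-filtered* total OFF time is not monotone in the
quorum (splitting an over-long run can move its pieces into bounds), while
the underlying quorum occupancy time is; the test suite asserts the latter.
Inputs with other channel counts require an explicit quorum — there is no
silent 12/16 rescaling.

**Fallback mode.** Recordings with very low MUA starve the flanking rule,
so `detect_fallback()` implements the simpler definition: any gap of at
least 50 ms in the merged all-channel spike train, edges included, with no
upper bound.

## Spike detection

Wideband traces are band-passed 300–12000 Hz with a zero-phase FIR filter
(order 512, Hamming design; zero phase preserves spike timing), then a
global common median reference subtracts the per-sample across-channel
median. Noise is estimated per channel as MAD/0.6745 and spikes are local
extrema beyond 4σ, negative-going by default (the extracellular convention;
the crossing polarity is configurable since either convention is
defensible). A 1-ms refractory pass keeps one event per waveform. Firing
rates use 2-s windows tiling the recording; a trailing partial window is
dropped rather than rescaled, avoiding an inflated-variance edge estimate.
At a 4σ threshold, pure-noise crossings arrive at roughly 2–4 events/s per
channel, so spurious fractions are only small relative to MUA-level firing
rates (tens to hundreds of Hz) — a property of the threshold rule itself, not
of this implementation.

## Spectral estimation

PSDs use 4-s DPSS (Slepian) windows, time–half-bandwidth NW = 4, 50%
overlap, with 2NW−1 = 7 tapers combined by eigenvalue weight — the standard
multitaper operating point. Tapers are computed from the symmetric
tridiagonal eigenproblem, with concentrations from the sinc kernel, and
cached per window length. Each window is mean-subtracted before tapering so
DC cannot leak into the delta band. PSDs are one-sided in power per Hz, so
the trapezoidal band integral of a unit-amplitude sinusoid recovers its
variance a²/2 — the calibration the tests assert. SWA is the 0.5–4 Hz
integral; condition SWA is expressed relative to the NREM mean of a baseline
reference window, normalized per channel and then averaged, and windows
whose centres fall in Artifact or Unsure bouts are masked from every
condition mean.

## OFF-locked waveform metrics

Snippets of LFP are aligned to OFF start, end, or midpoint and averaged per
channel (1 s each side; edge events dropped). The initiation slope is the
maximum of the Savitzky-Golay-smoothed first difference within ±10 samples
of the OFF start; termination uses OFF end; the peak amplitude is the
extremum within ±20 samples of the midpoint, signed according to the
recording polarity (positive-going slow waves for SOM-like recordings,
negative-going for ACR-like). Savitzky-Golay parameters are window 11,
order 3 at 400 Hz — about 25 ms of smoothing, enough to tame sample noise
without flattening a 30-ms rise; the filter is polynomial-exact, so a
linear ramp's slope is recovered without bias. Metrics are computed on the
event-locked average only, never per trial.

## STTC synchrony

For trains A and B within one epoch, T_A is the proportion of A's spikes
with a partner in B within ±5 ms, and P_A is the fraction of the epoch
already tiled by ±5 ms around A's own spikes (tiles clipped at epoch
boundaries, since P is a fraction of recording time and the per-epoch
recording is the bout). The default formula pairs each train's T with its
own P,

  STTC = ½ [ (T_A − P_A)/(1 − T_A·P_A) + (T_B − P_B)/(1 − T_B·P_B) ],

with the cross-paired variant available as
`sttc_params(formula = "cutts_eglen")`; both are exposed because the two
appear in the literature and differ in edge cases. The coefficient is
symmetric and provably bounded in [−1, 1]; empty trains yield a missing
value, not zero. Per-condition matrices average epochs in coefficient space
for display and in Fisher-Z space (z = atanh of r clipped to ±(1−10⁻⁶)) for
statistics; bouts shorter than 2·dt are skipped. Rate robustness — the
reason this statistic is used at all — holds when synchrony arises from
shared rate modulation (common silent periods), which is how both the test
suite and the generator exercise it.

## Conditions and statistics

`resolve_condition()` anchors windows on light onset and the end of sleep
deprivation: the 12-h baseline collects all NREM in the baseline light
period; recovery sleep is the first hour of *cumulative* NREM after SD,
truncated mid-bout so it totals exactly 3600 s (the only reading that
yields exactly one hour); the circadian-matched window repeats the
accumulation starting exactly 24 h before the recovery start. Too little
NREM returns a short window flagged `short = TRUE` rather than an error.

The statistics harness gates a paired/unpaired t-test versus Wilcoxon or
Mann-Whitney on Shapiro-Wilk normality (P > 0.05), reports Hedge's g (with
the small-sample correction J = 1 − 3/(4·df − 1); for paired designs on the
difference scores) or the rank-biserial correlation, adjusts families with
Benjamini-Hochberg, and for multi-group designs gates classic versus
Welch's ANOVA on Levene's test with Tukey HSD post-hocs. All underlying
tests delegate to `stats` and `car`; the package contributes the gating and
bookkeeping, and a null simulation verifies the gated paired test holds its
5% type-I error.

## Actigraphy

Pose tracks are reduced to a movement series — per frame transition and
node, Δx² + Δy², averaged across nodes — robust Z-scored
((m − median)/(1.4826·MAD)), thresholded at −mean(z)/std(z) (computed on
the z-series itself, the literal reading of the rule; a raw-series option
exists), and frames below threshold are labelled sleep. Degenerate series
(MAD zero) fall back to sd scaling, and if that is also zero every frame is
labelled wake — conservative for sleep claims. The adaptive threshold
separates the clusters when the session is wake-majority, so the movement
median sits in the wake cluster; this matches home-cage mice, which sleep
a bit under half of a 24-h day. The floor-texture novelty ratio is the
fraction of testing-window frames with the nose on the novel side.

## The synthetic generator

`simulate_session()` produces sessions with known ground truth under the
statistical structure the analysis assumes:

* **Vigilance states** follow a semi-Markov walk with log-normal bout
  durations and a diurnal rhythm (sleep-rich light phase, wake-rich dark
  phase, ~45% total sleep over a day — the regime reported for home-cage
  mice).
* **Population OFF events** arrive as a renewal process at
  `off_rate_nrem` = 0.5 events/s inside NREM bouts only, with log-normal
  durations (median 120 ms, log-sd 0.3 — inside the detectable 50–400 ms
  band; the defaults are
  chosen for detectability) and a 100-ms refractory ON gap so adjacent
  events never merge. Inter-onset gaps are drawn so the realized rate
  equals the nominal rate in expectation.
* **Channels** join each event with probability 0.95 and jitter entry and
  exit by Normal(0, 2 ms); the jitter sd is the generator's synchrony dial,
  and raising it provably reduces across-channel OFF overlap.
* **Spikes** are per-channel Poisson at 100 Hz (high-count multi-unit
  activity) outside the channel's own OFF intervals. The high rate also
  keeps the exponential-tail bias on detected OFF boundaries (~1/rate per
  flank) a few percent of the event duration.
* **LFP** is a sum of slow-wave kernels centred on each channel's own OFF
  midpoints over 1/f background noise (exponent 1, RMS 0.05 mV). The
  kernel is an asymmetric Gaussian bump (rise scale 30 ms, decay 120 ms,
  amplitude 0.3 mV, sign per polarity). A kernel that is smooth at onset
  was chosen deliberately: it admits the closed-form maximum rising slope
  A·e^(−1/2)/σ_r used as the waveform-metric oracle, which no
  onset-kinked kernel provides.
* **Pose** follows a random walk with log-normal step magnitudes (log-sd
  0.6 — the bursty, thin-left-tailed shape of rodent locomotion speeds)
  scaled per state, near-stationary in sleep.
* **Wideband** traces for detection tests place a stereotyped biphasic
  template (0.12 ms FWHM trough) at ground-truth spike times over Gaussian
  noise.

Identical seeds give bit-identical sessions. What the generator does *not*
emulate: real spike waveform diversity and overlap, non-stationary firing
rates within states, movement and electrode artifacts, volume conduction,
and true scorer disagreement in hypnograms. Passing the recovery tests
therefore demonstrates the correctness of the analysis chain under the
stated model, not performance on arbitrary real recordings.

## Protocol generation

`off_induction_protocol()` encodes the four-stage optogenetic OFF-induction
pattern (1 Hz/180 ms for 10 min, 2 Hz/140 ms for 10 min, 3 Hz/100 ms for
5 min with 45-s breaks, then 3 Hz/80 ms 5-min bouts with 30-s breaks
repeated until sleep onset), and `generate_protocol()` expands any staged
protocol into laser-on intervals, truncating at sleep onset so no light is
emitted after the animal falls asleep.

## Numerical choices and degenerate inputs

Time is seconds from session start throughout; intervals are half-open
[start, end), which removes every boundary ambiguity. Duration-bound
comparisons are made in milliseconds on the same floating-point
differences the sweep produces, and the brute-force oracles in the test
suite mirror that convention so borderline 50-ms gaps cannot flip between
implementations. Empty spike trains segment to no periods; empty recordings
in fallback mode are one long OFF; an STTC with an empty train is missing,
not zero; constant channels get σ = 0 with a warning and are skipped by
detection; single-channel recordings are zeroed by their own median
reference, with a warning. Wideband sample rates that are not integer
multiples of the 400-Hz LFP target decimate by the nearest integer factor
and record the realized rate.

## Validation problem sizes

The test suite validates each stage against independent brute-force
oracles and the generator's ground truth at desk scale: 1000 random
16-channel, 10-s instances for OFF-detection oracle equivalence; 10⁴
random pairs plus 500 exact-oracle instances and 200 independent-Poisson
pairs (5 Hz, 300 s) for STTC; 600 s of white noise and 120-s sinusoids for
spectral calibration; one 600-s NREM session for OFF parameter recovery;
10 seeds per level for the jitter and OFF-rate monotonicity sweeps (200-s
sessions); 16 channels × 20 s of wideband at SNR 10 for detection
recovery; twenty 24-h pose sessions for actigraphy; 2000 null replicates
for the type-I error of the gated test. These sizes were chosen so the
whole suite runs comfortably on a single CPU while leaving the Monte-Carlo
margins far from the asserted bounds.

## Known limitations

The spectral module offers no wavelet or irregular-resampling
alternatives and no artifact auto-rejection; artifact handling is by
hypnogram masking only. OFF detection offers no automatic fallback-mode
switching — mode is explicit configuration. Actigraphy consumes pose
coordinates; it neither trains pose models nor decodes video. The
statistics harness intentionally stops at the gated univariate tests and
Tukey post-hocs; mixed-effects modelling is out of scope.
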