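---
title: "Methods: heart-rate dose-response and cortico-cardiac coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate dose-response and cortico-cardiac coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, numerical choices and
design decisions behind `slowbeats`, in the order the pipeline applies
them. Nothing here reports an empirical result beyond what the test suite
and `scripts/acceptance.R` compute themselves.

## The scientific problem

Slow intravenous anesthetic inductions change cardiac physiology in a
dose-dependent way: mean heart rate rises approximately linearly with
effect-site concentration, high-frequency heart-rate variability
(respiratory sinus arrhythmia, a vagal index) shrinks, and the ECG R-wave
amplitude falls. Simultaneously the cortex produces ~1 Hz slow waves whose
incidence saturates with dose. The package quantifies these dose-response
relationships and, centrally, tests whether individual slow waves are
phase-locked to individual heartbeats — a coupling that, if present,
manifests as a non-uniform distribution of the interval between a slow
wave's onset and its preceding R-peak (the RS\_-1 interval) and as a
residual oscillation in the heartbeat-locked average ECG.

Because the original recordings are not freely redistributable, the
package ships a synthetic generator that reproduces the statistical
structure these analyses assume, with known ground truth. All validation
is parameter recovery: configure the generator with published estimates as
truth, run the full detection and estimation chain, and check the
estimates land on the configured values.

## ECG processing

`detect_r_peaks()` is an adaptive QRS detector in the
Pan-Tompkins/Hamilton family: zero-phase 8-16 Hz Butterworth band-pass
(order 3), rectified first difference smoothed over 80 ms, envelope peaks
classified against `threshold = noise + 0.3125 * (signal - noise)` where
the signal- and noise-peak estimates are exponential moving averages
(weight 1/8) of accepted and rejected peaks. A 0.2 s refractory period is
enforced, with two refinements found necessary in testing: a taller
envelope peak arriving inside the refractory window replaces the previous
acceptance (otherwise a P-wave bump can capture the detection and lock the
true R out), and a search-back pass with a halved threshold fires whenever
the gap since the last beat exceeds 1.5 times the running RR mean.
Detections are refined to the raw-signal maximum within ±50 ms. The
R-wave amplitude is measured on the raw, unfiltered ECG as the refined
peak value minus a local baseline (median over the 100 ms window ending
60 ms before the peak); baseline handling is a package choice, and because
it is a constant offset per morphology it cancels in the peak-minus-awake
amplitude *changes* the cohort statistics use. Subtracting the trace mean
before filtering makes detection exactly invariant to DC offset; all
thresholds are relative, so it is invariant to amplitude rescaling too.

## Heart-rate variability

Metrics are computed in non-overlapping 5-minute segments aligned to the
recording start (trailing partial segments dropped). RR intervals outside
0.24-6 s or differing more than 50% from the preceding interval are
excluded first. RMSSD is the root-mean-square successive RR difference in
ms. For the frequency domain the RR tachogram is interpolated to a uniform
4 Hz grid with a cubic spline, mean-detrended, and a Welch spectrum is
taken (128 s Hann segments, 50% overlap); LF is the trapezoid integral
over [0.04, 0.15) Hz, HF over [0.15, 0.4] Hz, and the HF peak frequency is
the spectral argmax inside the HF band. The interpolation rate, detrending
and estimator are not dictated by the published description of the
upstream toolbox; these are standard fixed choices, and the Welch
implementation is checked against Parseval and pure-tone oracles in the
tests.

## EEG preprocessing and slow-wave detection

Preprocessing is a phase-preserving (forward-backward) third-order
0.5-45 Hz Butterworth filter followed by anti-aliased polyphase resampling
to 100 Hz when needed, in that order. All zero-phase filtering in the
package extends the input by odd reflection over roughly three periods of
the lowest band edge before filtering; without this, finite-record
transients at the edges masquerade as slow deflections.

Detection runs on the 0.5-4 Hz (zero-phase) signal. Candidates are spans
between one downward zero crossing and the next containing exactly one
negative phase followed by a positive phase. A candidate is kept when its
negative-phase duration is 0.25-1.25 s and its trough magnitude reaches
the 99th percentile of the absolute filtered signal. Three readings of the
amplitude rule were open and are fixed as follows: the percentile is taken
over the *whole recording* (a single saturating anesthetic episode, so a
global threshold is meaningful), the criterion applies to the *trough*
magnitude (onset and duration are defined on the negative phase;
`amp_mode = "peak2peak"` is the alternative), and the wave period is
onset-to-next-onset so `frequency = 1/(end - onset)` exactly. Onsets are
interpolated between samples. Events within 2 s of the record boundaries
are discarded as unreliable. Because the threshold is relative, detection
counts are invariant to amplitude rescaling.

Note one consequence of detecting on a band-passed trace: a wave whose
negative phase is longer than the high-pass period (say 1.5 s) is
reshaped by the 0.5 Hz edge into shorter lobes. The duration ceiling is
enforced on the filtered signal, which is what the detector can observe;
the tests assert exactly this behavior.

## RS intervals and proportional Shannon entropy

For each slow-wave onset the 4 nearest preceding and 4 nearest following
R-peaks are collected ("8 closest heartbeats"; a strict
nearest-by-absolute-distance variant was considered and rejected because
the symmetric 4+4 form keeps the RS\_-1 column well defined); a beat
exactly at the onset counts as preceding with RS\_-1 = 0. Waves without 4
beats on each side are skipped and counted.

A moving window of 40 waves (advancing one wave at a time) bins that
window's RS\_-1 values into a 10-bin histogram with outer limits 0 and the
mean heart period over the span the window covers; values beyond the limit
are excluded, not clipped, and the exclusion count is kept. The statistic
is the proportional Shannon entropy `SH_P = -sum(P_b ln P_b) / ln 10`,
which is 0 when all intervals share a bin (perfect phase concentration)
and 1 for exactly uniform counts. The printed formula chain in the source
material omits the minus sign on SH while defining `SH_max = -log(1/N)`;
only the signed convention keeps `SH_P` in [0, 1], so that is what is
implemented. Natural logarithms are used throughout; the ratio makes the
base irrelevant. The subject summary is the mean `SH_P` across windows.

### Surrogate calibration, and why there are two modes

The published null is explicit: 10,000 surrogate series of 200 U(0,1)
draws each, one 10-bin histogram per series, threshold at the 0.1st
percentile of the surrogate `SH_P` distribution (significance P = 0.001).
Both candidate readings of the surrogate construction were brute-forced
before implementation: binning each series once reproduces the printed
threshold 0.970 (and the second-order chi-square expansion
`1 - qchisq(0.999, 9) / (2 * 200 * ln 10) = 0.9697` confirms it);
pushing each series through the 40-wave moving-window statistic instead
gives a null centered near 0.95 — the plug-in entropy bias of a 40-sample
histogram, `(N - 1)/(2 * 40 * ln N)`, is five times that of a 200-sample
one. The single-histogram mode is therefore the published calibration,
but it is *not* bias-matched to the subject statistic; comparing a
windowed subject mean to the single-histogram threshold is conservative
in the coupled direction. `surrogate_threshold(mode = "windowed")`
provides the bias-matched null, and the pipeline uses it for its
coupling verdict while reporting the published calibration alongside.

### Time-locked averaging

±2 s of ECG and EEG are epoched around each wave onset (waves without
full coverage dropped; at least 10 required) and averaged within, then
across, subjects with equal subject weight. The ECG is additionally
band-filtered 0.5-1.5 Hz on the full trace before epoching; the reported
`peak_lag` is the lag of the maximum of this band-filtered average within
[-1, 0) s, i.e. the dominant pre-onset heartbeat position. The band
default is 0.5-1.5 Hz with the wider 0.5-4 Hz variant available, and the
lock point can be switched from onset to trough for robustness runs.

## The synthetic generator

### Volunteer arm

The effect-site concentration is piecewise linear over four phases
(defaults 600/2880/600/2880 s, jointly scalable; no pharmacokinetic model
is attempted). Heartbeats are laid down by iterating
`RR(t) = 60 / (hr_intercept + hr_slope * Ce(t)) + modulation`, with a
respiratory sinus-arrhythmia term (0.25 Hz, 40 ms shrinking by 8 ms per
ug/ml) and a low-frequency term (15 ms at 0.095 Hz). Beat timing is thus
deterministic given the configuration; stochasticity enters through wave
placement, per-beat amplitude noise and trace noise. Defaults printed in
the emulated study are used as-is: heart rate 56.1 + 4.23 bpm/(ug/ml),
R amplitude 966 uV falling 20.75 uV per ug/ml (83 uV over the full ramp),
coupling lag 447 ms.

The ECG is a train of analytic Gaussian P-QRS-T bumps plus white noise
(3 uV); only the R bump is amplitude-modulated, since only the R amplitude
is quantified downstream (dose-dependent T-wave morphology change is
deliberately not modeled). The T bump (120 uV, 30 ms width) and R width
(14 ms) were set so that the 0.5-1.5 Hz-filtered beat peaks at the R wave
(+8 ms) rather than at the broad T wave — the emulated phenomenon is a
heartbeat-evoked average peaking at the R peak, and a T-dominated template
would displace it by construction.

The EEG is 1/f background noise (exponent 1, 10 uV SD) plus biphasic slow
waves: a negative-then-positive full sine (frequency 1.0 ± 0.08 Hz,
trough amplitude 90 ± 4 uV) preceded by a 0.35-amplitude positive
half-sine run-up. The run-up matters: an isolated full-sine cycle loses
sub-0.5 Hz content to the detection filter's high-pass edge, which shifts
the detected downward-crossing onset tens of milliseconds late; the run-up
(itself physiologically sensible — slow waves ride on ongoing delta
activity) zeroes that shift so the recorded ground-truth onset is the
onset an ideal detector would report. Wave incidence follows a sigmoid in
concentration saturating at 5 waves/min (midpoint 2 ug/ml, width 0.35,
zero below 1 ug/ml); incidence rates are not published, and 5/min keeps
waves under ~4% of samples so that the 99th-percentile amplitude criterion
stays below the wave-amplitude distribution (at 8/min the threshold climbs
into the distribution and recall drops — the detection-recall requirement
fixes the admissible range). Each wave is onset-locked 447 ms after the
nearest preceding R-peak with probability `sw_coupling_prob` (default
0.8), otherwise left at its uniformly random candidate time; a minimum
0.3 s separation is enforced.

The cohort wrapper draws per-subject dose-response parameters
(SD 2 bpm / 0.8 bpm-per-ug/ml / 50 uV / 5 uV around the defaults). These
between-subject spreads are deliberately tighter than the observed spread
in the emulated study (which includes measurement error); they are sized
so a 16-subject synthetic cohort estimates the configured truth with
useful precision while still exercising between-subject variance.

### Clinical arm

Per patient: demographics drawn (age 61-86, BMI 27 ± 4 truncated, ASA 2/3,
31% female), drug trajectories generated, and heart rate computed from the
eleven-coefficient fixed-effect model (defaults are the published clinical
estimates) plus a patient random intercept (7 bpm) and white residual
noise (2 bpm), sampled every 5 s for 60 min; spike artifacts outside
10-250 bpm are injected at 6/h. Trajectories are smooth on the 2-minute
smoothing scale and their timing is randomized per patient (propofol decay
constant, desflurane onset delay, fentanyl bolus jitter): with shared
schedules the drug regressors are nearly collinear functions of elapsed
time across the cohort, and any smoothing distortion transfers into
coefficient bias.

## Clinical preprocessing and the mixed model

Heart rates outside 10-250 bpm become missing first; then a centered
moving median, ignoring missing values, smooths each patient's series. The
window is 25 samples (odd; 24 samples is exactly 2 min at 5 s): an odd
centered median reproduces locally monotone data exactly, which makes the
filter idempotent away from trajectory extrema. All-missing patients are
dropped with a warning.

`fit_clinical_glm()` fits, by REML, heart rate on age, BMI, ASA (numeric
2/3), a female indicator, the three drug concentrations and their pairwise
interactions, with a per-patient random intercept; intervals are
large-sample Wald, p-values Satterthwaite. One deliberate deviation from a
literal reading of the published procedure: a 25-sample moving median
makes neighbouring residuals strongly dependent (integrated
autocorrelation time ≈ 23 samples for white input), so per-observation
Wald intervals computed from every 5 s sample would be roughly
`sqrt(23) ≈ 5` times too narrow and parameter-recovery coverage would
collapse to ~30%. The fit therefore thins each patient's smoothed series
to one observation per smoothing window (skipping the half-window edges,
where the partial-window median is biased exactly where trajectories move
fastest) before fitting; `thin = 1` restores the literal fit when
interval calibration is not a concern. With thinning, replicate
simulations recover the configured coefficients with approximately nominal
coverage, which is what the test suite asserts (using the one-sided
binomial bound appropriate for 50 replicates).

Cohort statistics elsewhere are standard: Spearman with mid-rank ties on
5-minute segments, OLS with 95% CIs, Cohen's d with the pooled (n-1)
standard deviation, Pearson for the subject-level heart-rate /
slow-wave-frequency association.

## Problem sizes, determinism and limitations

The tests and the acceptance script run the volunteer arm at quarter-scale
phases (29 min per recording, 16 and 8 subjects) and event-level
simulations at full scale; the clinical arm at 96 patients × 60 min for
recovery checks and 40 × 40 min for the 50-replicate coverage study.
These sizes give Monte-Carlo error comfortably inside the assertion
tolerances. Every stochastic element is seeded; identical configurations
and seeds reproduce recordings and pipeline summaries byte for byte, and
the RNG state of the caller is restored afterwards.

What passing on synthetic data does and does not show: the generator
emulates the *statistical structure* the analyses assume — template
beats, sinusoidal RR modulation, clean single-channel EEG, stylized wave
shapes, additive stationary noise. It does not contain ectopy, movement or
electrode artifacts, non-stationary respiration, multi-channel volume
conduction (including the common-average reference's effect on ECG
amplitude scale in the real recordings), pathologic morphology, or
model-misspecified clinical confounding. Recovery on synthetic data
validates the estimators' correctness, not their robustness to everything
real recordings contain. The RS-interval entropy statistic also inherits
the known finite-sample bias discussed above; comparisons should always
use the bias-matched surrogate mode unless reproducing the published
calibration is the point.
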