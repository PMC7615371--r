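# slowbeats

Cortico-cardiac coupling analysis for anesthesia ECG/EEG in R.

During slow propofol inductions the heart rate rises roughly linearly with
effect-site concentration, high-frequency (vagally mediated) heart-rate
variability collapses, the ECG R-wave amplitude falls, and frontal EEG slow
waves appear and saturate with dose. Beyond these dose-response effects,
individual slow waves are not independent of the heart: a heartbeat
preferentially precedes the slow-wave onset by a few hundred milliseconds.
`slowbeats` implements the full analysis chain needed to quantify these
effects, for researchers in anesthesia neurophysiology and autonomic
physiology:

- **ECG**: adaptive R-peak detection (Pan-Tompkins/Hamilton family:
  8-16 Hz band-pass, rectified-derivative envelope, adaptive
  signal/noise-peak thresholds, 0.2 s refractory, search-back), instantaneous
  heart rate, baseline-subtracted R-wave amplitudes, averaged beat templates.
- **HRV**: RMSSD and Welch-spectral LF (0.04-0.15 Hz) / HF (0.15-0.4 Hz)
  power, their ratio, and the HF peak frequency in 5-minute segments.
- **EEG**: zero-phase 0.5-45 Hz preprocessing, slow-wave detection by
  amplitude (99th percentile of the 0.5-4 Hz signal) and negative-phase
  duration (0.25-1.25 s) criteria, and 0.5-1.5 Hz slow-wave activity.
- **Coupling**: for each slow wave, the RS intervals to the 8 nearest
  heartbeats; the proportional Shannon entropy of the RS\_-1 distribution
  in moving 40-wave windows,

  SH = -sum(P_b log P_b),  SH_max = log N,  SH_P = SH / SH_max  (N = 10 bins),

  so SH_P = 0 under perfect phase-locking and SH_P = 1 under no coupling;
  a Monte-Carlo uniform-surrogate threshold (10,000 series of 200 U(0,1)
  draws; 0.1st percentile = 0.970) with a bias-matched windowed variant;
  and time-locked (+/-2 s) ECG/EEG averaging around slow-wave onsets.
- **Cohort statistics**: Spearman/OLS dose-response on 5-minute segments,
  Cohen's d, and for long-format clinical tables a mixed-effects model
  `HR ~ age + BMI + ASA + sex + prop + fent + des + prop:fent + prop:des +
  fent:des + (1 | patient)` with artifact exclusion (10-250 bpm) and 2-min
  moving-median smoothing.
- **Synthetic generator**: coupled ECG+EEG volunteer recordings and clinical
  cohorts with known ground truth (beat times, wave onsets, coupling flags),
  used to validate every stage without access to real recordings.

## Worked example

```r
library(slowbeats)

cfg <- volunteer_sim_config(phase_scale = 0.25, seed = 3)  # 29-min recording
rec <- simulate_volunteer(cfg)
rec
#> <volunteer_recording: 1740 s, 1873 beats, 73 slow waves (kappa = 0.8)>

beats <- detect_r_peaks(rec$ecg)
beats
#> <beat_series: 1873 beats, mean RR 0.929 s>
match_beats(beats$r_times, rec$truth_beats, tol = 0.01)$recall
#> [1] 1

eeg   <- preprocess_eeg(rec$eeg)
waves <- detect_slow_waves(eeg)
ent   <- windowed_entropy(rs_intervals(beats, waves), beats)
ent
#> <entropy_result: 32 windows, mean SH_P = 0.365>

surrogate_threshold(seed = 1)
#> <surrogate_calibration (histogram): 10000 series of 200, SH_P threshold at the 0.1% percentile = 0.9707>

time_locked_average(rec$ecg, eeg, waves)
#> <time_locked_average: 71 waves, band ECG peak at 464 ms before onset>
```

The recording above was generated with 80% of slow waves onset-locked
447 ms after the preceding R-peak. The detected beats are perfect
(recall 1), the subject's windowed entropy (0.365) falls far below the
uniform-surrogate significance threshold (0.970), i.e. the waves are
judged coupled to the heartbeat, and the band-filtered heartbeat-locked
ECG average peaks 464 ms before wave onset, recovering the configured lag.

Whole-cohort runs with per-subject CSV tables, EDF export, group
dose-response statistics and a JSON summary:

```r
run_volunteer_pipeline("out_vol", n_subjects = 16, seed = 1)
run_clinical_pipeline("out_clin", clinical_sim_config(seed = 1))
```

or from a shell: `Rscript inst/scripts/ccpipe.R run-volunteer --out out_vol
--subjects 16 --seed 1 --scale 0.25`.

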