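#' Configuration for the synthetic volunteer recording generator
#'
#' Defines the study conditions emulated by [simulate_volunteer()]: a slow
#' effect-site concentration ramp (awake / induction / peak / emergence), a
#' heart rate that rises linearly with concentration, respiratory sinus
#' arrhythmia that shrinks with dose, an R-wave amplitude that falls with
#' dose, and cortical slow waves whose incidence saturates with dose and
#' whose onsets are, with probability `sw_coupling_prob`, phase-locked at a
#' fixed lag after the preceding heartbeat.
#'
#' Dose-response defaults are set from the fitted volunteer relationships
#' (heart rate 56.1 + 4.23 bpm per ug/ml; R-wave amplitude 966 uV at
#' baseline falling by 83 uV over the 4 ug/ml ramp; coupling lag 447 ms).
#'
#' @param phase_durations named seconds for the awake, induction, peak and
#'   emergence phases (defaults 600/2880/600/2880).
#' @param phase_scale single multiplier applied to all four durations.
#' @param ce_max peak effect-site concentration, ug/ml.
#' @param hr_intercept,hr_slope heart rate model: bpm at zero concentration
#'   and bpm per ug/ml.
#' @param rsa_freq respiration frequency driving sinus arrhythmia, Hz.
#' @param rsa_amp_base,rsa_amp_slope RR modulation depth in ms at zero
#'   concentration and its change per ug/ml (negative: vagally mediated
#'   high-frequency variability shrinks with dose).
#' @param lf_amp,lf_freq low-frequency RR modulation (ms, Hz).
#' @param rwa_base,rwa_slope R-wave amplitude in uV at zero concentration
#'   and uV per ug/ml (negative).
#' @param rwa_noise_sd per-beat amplitude noise, uV.
#' @param ecg_noise_sd additive white noise on the ECG trace, uV.
#' @param sw_rate_max saturating slow-wave incidence, waves per minute.
#' @param sw_ce50,sw_rate_k sigmoid midpoint (ug/ml) and width (ug/ml) of
#'   the incidence curve.
#' @param sw_ce_threshold concentration below which no slow waves occur.
#' @param sw_coupling_prob kappa in \[0, 1\]: probability a slow wave is
#'   onset-locked to the preceding R-peak.
#' @param sw_coupling_lag seconds from R-peak to slow-wave onset for
#'   coupled waves.
#' @param sw_lock_point "onset" locks the downward zero crossing to the
#'   R-peak + lag; "trough" locks the trough instead (robustness variant).
#' @param sw_freq_mean,sw_freq_sd per-wave frequency distribution, Hz.
#' @param sw_freq_hr_link Hz of slow-wave frequency per bpm of
#'   `hr_intercept` deviation from 56.1 (0 disables; used to emulate the
#'   between-subject heart-rate / slow-wave-frequency association).
#' @param sw_amp,sw_amp_sd trough amplitude distribution, uV.
#' @param eeg_noise_exponent,eeg_noise_scale background 1/f^alpha noise:
#'   spectral exponent and standard deviation in uV.
#' @param fs_ecg,fs_eeg sampling rates, Hz (>= 250 and >= 50).
#' @param seed integer RNG seed; every stochastic element is reproducible
#'   given the seed.
#' @return A validated list of class `volunteer_sim_config`.
#' @seealso [simulate_volunteer()], [simulate_volunteer_cohort()]
#' @export
volunteer_sim_config <- function(
    phase_durations = c(awake = 600, induction = 2880, peak = 600,
                        emergence = 2880),
    phase_scale = 1,
    ce_max = 4,
    hr_intercept = 56.1, hr_slope = 4.23,
    rsa_freq = 0.25, rsa_amp_base = 40, rsa_amp_slope = -8,
    lf_amp = 15, lf_freq = 0.095,
    rwa_base = 966, rwa_slope = -20.75, rwa_noise_sd = 20,
    ecg_noise_sd = 3,
    sw_rate_max = 5, sw_ce50 = 2, sw_rate_k = 0.35, sw_ce_threshold = 1,
    sw_coupling_prob = 0.8, sw_coupling_lag = 0.447,
    sw_lock_point = c("onset", "trough"),
    sw_freq_mean = 1.0, sw_freq_sd = 0.08, sw_freq_hr_link = 0,
    sw_amp = 90, sw_amp_sd = 4,
    eeg_noise_exponent = 1.0, eeg_noise_scale = 10,
    fs_ecg = 500, fs_eeg = 100, seed = 1) {
  cfg <- list(
    phase_durations = phase_durations, phase_scale = phase_scale,
    ce_max = ce_max, hr_intercept = hr_intercept, hr_slope = hr_slope,
    rsa_freq = rsa_freq, rsa_amp_base = rsa_amp_base,
    rsa_amp_slope = rsa_amp_slope, lf_amp = lf_amp, lf_freq = lf_freq,
    rwa_base = rwa_base, rwa_slope = rwa_slope,
    rwa_noise_sd = rwa_noise_sd, ecg_noise_sd = ecg_noise_sd,
    sw_rate_max = sw_rate_max, sw_ce50 = sw_ce50, sw_rate_k = sw_rate_k,
    sw_ce_threshold = sw_ce_threshold,
    sw_coupling_prob = sw_coupling_prob,
    sw_coupling_lag = sw_coupling_lag,
    sw_lock_point = match.arg(sw_lock_point),
    sw_freq_mean = sw_freq_mean, sw_freq_sd = sw_freq_sd,
    sw_freq_hr_link = sw_freq_hr_link,
    sw_amp = sw_amp, sw_amp_sd = sw_amp_sd,
    eeg_noise_exponent = eeg_noise_exponent,
    eeg_noise_scale = eeg_noise_scale,
    fs_ecg = fs_ecg, fs_eeg = fs_eeg, seed = seed)
  validate_volunteer_config(cfg)
  structure(cfg, class = "volunteer_sim_config")
}

validate_volunteer_config <- function(cfg) {
  stopifnot(length(cfg$phase_durations) == 4, all(cfg$phase_durations > 0),
            cfg$phase_scale > 0, cfg$ce_max > 0)
  if (cfg$sw_coupling_prob < 0 || cfg$sw_coupling_prob > 1)
    stop("sw_coupling_prob must be in [0, 1]")
  if (cfg$fs_ecg < 250) stop("fs_ecg must be >= 250 Hz")
  if (cfg$fs_eeg < 50) stop("fs_eeg must be >= 50 Hz")
  hr_lo <- min(cfg$hr_intercept, cfg$hr_intercept + cfg$hr_slope * cfg$ce_max)
  hr_hi <- max(cfg$hr_intercept, cfg$hr_intercept + cfg$hr_slope * cfg$ce_max)
  if (hr_lo <= 10 || hr_hi >= 250)
    stop("configured heart rate leaves the (10, 250) bpm range")
  invisible(cfg)
}

#' Effect-site concentration profile of a simulated recording
#'
#' Piecewise-linear concentration: zero during the awake phase, a linear
#' ramp to `ce_max` during induction, constant at `ce_max` during peak
#' anesthesia, then a linear return to zero during emergence.
#'
#' @param config a [volunteer_sim_config()].
#' @param t times in seconds (vectorized).
#' @return Concentration in ug/ml at each `t`.
#' @export
ce_profile <- function(config, t) {
  d <- config$phase_durations * config$phase_scale
  b <- cumsum(c(0, d)) # phase boundaries
  ce <- numeric(length(t))
  idx <- t >= b[2] & t < b[3]
  ce[idx] <- config$ce_max * (t[idx] - b[2]) / d[2]
  idx <- t >= b[3] & t < b[4]
  ce[idx] <- config$ce_max
  idx <- t >= b[4] & t <= b[5]
  ce[idx] <- config$ce_max * (1 - (t[idx] - b[4]) / d[4])
  ce[t > b[5]] <- 0
  ce
}

#' Phase windows of a simulated recording
#'
#' @param config a [volunteer_sim_config()].
#' @return data.frame with columns phase, start, end (seconds).
#' @export
phase_windows <- function(config) {
  d <- config$phase_durations * config$phase_scale
  b <- cumsum(c(0, d))
  data.frame(phase = c("awake", "induction", "peak", "emergence"),
             start = b[1:4], end = b[2:5])
}

# Analytic P-QRS-T beat shape built from Gaussian bumps. The R bump is kept
# separate so only the R-wave amplitude is modulated with dose; the other
# waves are fixed (morphological QT changes are deliberately not modeled).
ecg_beat_shapes <- function(fs) {
  lag <- seq(-0.25, 0.45, by = 1 / fs)
  g <- function(c0, a, s) a * exp(-(lag - c0)^2 / (2 * s^2))
  # T-wave size/width keeps the low-frequency (0.5-1.5 Hz) beat energy
  # R-dominated, as in the recordings the generator emulates, where the
  # heartbeat-evoked ECG average peaks at the R wave itself.
  fixed <- g(-0.17, 100, 0.025) + g(-0.025, -120, 0.008) +
    g(0.025, -150, 0.008) + g(0.25, 120, 0.03)
  list(lag = lag, fixed = fixed, r = g(0, 1, 0.014))
}

#' Simulate a coupled ECG/EEG volunteer recording
#'
#' Generates a full recording with known ground truth. Heartbeats are laid
#' down by iterating RR intervals from the instantaneous rate
#' `hr_intercept + hr_slope * Ce(t)` modulated by respiratory (RSA) and
#' low-frequency sinusoidal RR terms; the ECG is a train of analytic
#' P-QRS-T templates whose R amplitude follows `rwa_base + rwa_slope *
#' Ce(t)` plus per-beat noise. The EEG is 1/f^alpha background noise plus
#' biphasic (negative-then-positive full-sine) slow waves drawn from an
#' inhomogeneous Poisson process whose rate saturates with concentration;
#' each wave is, with probability `sw_coupling_prob`, onset-placed at
#' `sw_coupling_lag` after the nearest preceding R-peak, otherwise left at
#' its uniformly random candidate time.
#'
#' @param config a [volunteer_sim_config()].
#' @param events_only if `TRUE`, skip trace synthesis and return only the
#'   ground-truth beat and slow-wave events (fast path for event-level
#'   statistics).
#' @return An object of class `volunteer_recording` with elements `ecg`,
#'   `eeg` ([signal_trace()]; absent if `events_only`), `ce_series`
#'   (data.frame `t_s`, `ce_ugml`, one row per second), `truth_beats`
#'   (R-peak times, s), `truth_rwa` (per-beat R amplitudes, uV),
#'   `truth_sw` (data.frame of slow-wave onset, frequency, amplitude,
#'   coupled flag), and the `config`.
#' @export
simulate_volunteer <- function(config, events_only = FALSE) {
  validate_volunteer_config(config)
  with_local_seed(config$seed, {
    d <- config$phase_durations * config$phase_scale
    total <- sum(d)

    # --- heartbeats ---------------------------------------------------
    n_guess <- ceiling(total * (config$hr_intercept +
                                  abs(config$hr_slope) * config$ce_max) / 60) + 16L
    beats <- numeric(n_guess)
    n <- 0L
    t <- 0.5 # first beat shortly after recording start
    while (t < total) {
      n <- n + 1L
      beats[n] <- t
      ce <- ce_profile(config, t)
      hr <- config$hr_intercept + config$hr_slope * ce
      mod_ms <- (config$rsa_amp_base + config$rsa_amp_slope * ce) *
        sin(2 * pi * config$rsa_freq * t) +
        config$lf_amp * sin(2 * pi * config$lf_freq * t)
      rr <- 60 / hr + mod_ms / 1000
      if (rr <= 0.24 || rr >= 6)
        stop(sprintf("configuration produces RR = %.3f s outside (0.24, 6)",
                     rr))
      t <- t + rr
    }
    beats <- beats[seq_len(n)]
    ce_beats <- ce_profile(config, beats)
    truth_rwa <- config$rwa_base + config$rwa_slope * ce_beats +
      rnorm(n, 0, config$rwa_noise_sd)
    truth_rwa <- pmax(truth_rwa, 50)

    # --- slow-wave events ---------------------------------------------
    sw_rate <- function(ce) { # waves per second
      r <- config$sw_rate_max /
        (1 + exp(-(ce - config$sw_ce50) / config$sw_rate_k))
      r[ce < config$sw_ce_threshold] <- 0
      r / 60
    }
    lam_max <- config$sw_rate_max / 60
    n_cand <- rpois(1, lam_max * total)
    cand <- sort(runif(n_cand, 0, total))
    keep <- runif(n_cand) < sw_rate(ce_profile(config, cand)) / lam_max
    cand <- cand[keep]
    coupled <- runif(length(cand)) < config$sw_coupling_prob
    freq_mean <- config$sw_freq_mean +
      config$sw_freq_hr_link * (config$hr_intercept - 56.1)
    freqs <- pmin(pmax(rnorm(length(cand), freq_mean, config$sw_freq_sd),
                       0.7), 1.4)
    amps <- pmax(rnorm(length(cand), config$sw_amp, config$sw_amp_sd), 60)
    onsets <- cand
    if (any(coupled)) {
      prev_idx <- findInterval(cand[coupled], beats)
      lag <- config$sw_coupling_lag
      if (config$sw_lock_point == "trough")
        lag <- lag - 1 / (4 * freqs[coupled]) # trough sits a quarter period in
      shifted <- ifelse(prev_idx >= 1, beats[pmax(prev_idx, 1)] + lag,
                        cand[coupled])
      onsets[coupled] <- shifted
    }
    ord <- order(onsets)
    onsets <- onsets[ord]; coupled <- coupled[ord]
    freqs <- freqs[ord]; amps <- amps[ord]
    # enforce separation and margins so waveforms do not overlap
    keep <- logical(length(onsets))
    last_end <- -Inf
    for (i in seq_along(onsets)) {
      dur <- 1 / freqs[i]
      if (onsets[i] > last_end + 0.3 && onsets[i] > 2.5 &&
          onsets[i] + dur < total - 2.5) {
        keep[i] <- TRUE
        last_end <- onsets[i] + dur
      }
    }
    truth_sw <- data.frame(onset = onsets[keep], frequency = freqs[keep],
                           amplitude = amps[keep], coupled = coupled[keep])

    ce_series <- data.frame(t_s = 0:(floor(total) - 1))
    ce_series$ce_ugml <- ce_profile(config, ce_series$t_s)

    rec <- list(ce_series = ce_series, truth_beats = beats,
                truth_rwa = truth_rwa, truth_sw = truth_sw, config = config)

    if (!events_only) {
      # --- ECG trace --------------------------------------------------
      fs <- config$fs_ecg
      npt <- floor(total * fs)
      shapes <- ecg_beat_shapes(fs)
      w <- length(shapes$lag)
      off <- which.min(abs(shapes$lag)) # index of lag 0 in the template
      x <- rnorm(npt, 0, config$ecg_noise_sd)
      i0 <- round(beats * fs) + 1L - (off - 1L)
      for (k in seq_len(n)) {
        a <- i0[k]; b <- a + w - 1L
        if (a < 1L || b > npt) next
        x[a:b] <- x[a:b] + shapes$fixed + truth_rwa[k] * shapes$r
      }
      rec$ecg <- signal_trace(x, fs, "ECG")

      # --- EEG trace --------------------------------------------------
      fe <- config$fs_eeg
      npe <- floor(total * fe)
      e <- pink_noise(npe, config$eeg_noise_exponent, config$eeg_noise_scale)
      # Each wave is a negative-then-positive full sine preceded by a
      # smaller positive half-sine run-up (amplitude 0.35x). The run-up
      # mimics the ongoing delta activity slow waves ride on and removes
      # the spurious onset-crossing shift an isolated cycle would acquire
      # under the 0.5 Hz high-pass of the detection filter.
      for (k in seq_len(nrow(truth_sw))) {
        f0 <- truth_sw$frequency[k]
        amp <- truth_sw$amplitude[k]
        dur <- 1 / f0
        a <- floor((truth_sw$onset[k] - dur / 2) * fe) + 1L
        b <- min(floor((truth_sw$onset[k] + dur) * fe) + 1L, npe)
        if (a < 1L) a <- 1L
        tt <- ((a:b) - 1) / fe - truth_sw$onset[k]
        wv <- ifelse(tt < 0, 0.35 * amp * sin(2 * pi * f0 * (tt + dur / 2)),
                     -amp * sin(2 * pi * f0 * tt))
        e[a:b] <- e[a:b] + wv
      }
      rec$eeg <- signal_trace(e, fe, "EEG")
    }
    structure(rec, class = "volunteer_recording")
  })
}

#' @export
print.volunteer_recording <- function(x, ...) {
  cat(sprintf(
    "<volunteer_recording: %.0f s, %d beats, %d slow waves (kappa = %g)%s>\n",
    sum(x$config$phase_durations * x$config$phase_scale),
    length(x$truth_beats), nrow(x$truth_sw), x$config$sw_coupling_prob,
    if (is.null(x$ecg)) ", events only" else ""))
  invisible(x)
}

#' Simulate a cohort of volunteer recordings
#'
#' Draws per-subject dose-response parameters around the configured values
#' (normal between-subject variation) and simulates each subject with a
#' distinct seed derived from `seed`.
#'
#' @param n_subjects number of volunteers.
#' @param config baseline [volunteer_sim_config()] shared by the cohort.
#' @param seed cohort-level seed; subject seeds are derived from it.
#' @param between named list of between-subject standard deviations for
#'   `hr_intercept`, `hr_slope`, `rwa_base`, `rwa_slope` (bpm, bpm per
#'   ug/ml, uV, uV per ug/ml).
#' @param events_only passed to [simulate_volunteer()].
#' @return List of `volunteer_recording` objects.
#' @export
simulate_volunteer_cohort <- function(n_subjects = 16,
                                      config = volunteer_sim_config(),
                                      seed = 1,
                                      between = list(hr_intercept_sd = 2,
                                                     hr_slope_sd = 0.8,
                                                     rwa_base_sd = 50,
                                                     rwa_slope_sd = 5),
                                      events_only = FALSE) {
  stopifnot(n_subjects >= 1)
  pars <- with_local_seed(seed, data.frame(
    hr_intercept = rnorm(n_subjects, config$hr_intercept,
                         between$hr_intercept_sd),
    hr_slope = rnorm(n_subjects, config$hr_slope, between$hr_slope_sd),
    rwa_base = rnorm(n_subjects, config$rwa_base, between$rwa_base_sd),
    rwa_slope = rnorm(n_subjects, config$rwa_slope, between$rwa_slope_sd)))
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$hr_intercept <- pars$hr_intercept[i]
    cfg$hr_slope <- pars$hr_slope[i]
    cfg$rwa_base <- pars$rwa_base[i]
    cfg$rwa_slope <- pars$rwa_slope[i]
    cfg$seed <- (as.integer(seed) %% 1000000L) * 1000L + i
    simulate_volunteer(cfg, events_only = events_only)
  })
}

#' Write a volunteer recording to disk
#'
#' Writes the signals as one EDF file (channels "ECG" and "EEG"), the
#' concentration series and ground-truth events as CSV sidecars, and the
#' generating configuration (including the seed) as a round-trippable
#' key-value YAML file.
#'
#' @param rec a `volunteer_recording` from [simulate_volunteer()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_volunteer_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(rec$ecg))
    write_edf(list(ECG = rec$ecg, EEG = rec$eeg),
              file.path(dir, "recording.edf"))
  write.csv(rec$ce_series, file.path(dir, "concentration.csv"),
            row.names = FALSE)
  write.csv(data.frame(r_time_s = rec$truth_beats, rwa_uv = rec$truth_rwa),
            file.path(dir, "truth_beats.csv"), row.names = FALSE)
  write.csv(rec$truth_sw, file.path(dir, "truth_slow_waves.csv"),
            row.names = FALSE)
  write_sim_config(rec$config, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Write / read a simulation configuration as key-value text
#'
#' @param config a `volunteer_sim_config` or `clinical_sim_config`.
#' @param path YAML file path.
#' @return `read_sim_config()` returns the validated configuration object.
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  # named vectors must become maps to keep their names through YAML
  lst <- lapply(lst, function(x)
    if (!is.null(names(x))) as.list(x) else x)
  lst$.class <- class(config)[1]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class %||% "volunteer_sim_config"
  lst$.class <- NULL
  maker <- if (cls == "clinical_sim_config") clinical_sim_config
           else volunteer_sim_config
  fixup <- function(x) if (is.list(x)) unlist(x) else x
  do.call(maker, lapply(lst, fixup))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
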