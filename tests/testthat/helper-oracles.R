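# Independent oracles and tiny fixture builders used across the suite.

# Histogram entropy computed through cut()/table(), independent of the
# findInterval/tabulate path used by proportional_entropy().
entropy_oracle <- function(values, lower, upper, n_bins = 10) {
  v <- values[values >= lower & values <= upper]
  if (!length(v)) return(NA_real_)
  breaks <- seq(lower, upper, length.out = n_bins + 1)
  p <- as.numeric(table(cut(v, breaks, include.lowest = TRUE))) / length(v)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins)
}

# Minimal ECG: a train of Gaussian R bumps at the requested beat times,
# independent of the package's beat-template generator.
make_bump_train <- function(beat_times, dur, fs = 500, amp = 1000,
                            sigma = 0.012, noise_sd = 0) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rnorm(n, 0, noise_sd)
  for (b in beat_times) {
    sel <- which(abs(t - b) < 8 * sigma)
    x[sel] <- x[sel] + amp * exp(-(t[sel] - b)^2 / (2 * sigma^2))
  }
  signal_trace(x, fs, "ECG")
}

# Beat times with constant heart rate (bpm), starting at t0.
constant_rate_beats <- function(hr_bpm, dur, t0 = 0.5) {
  seq(t0, dur - 0.5, by = 60 / hr_bpm)
}
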