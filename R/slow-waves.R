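#' Preprocess raw EEG
#'
#' Forward-backward (phase-preserving) third-order Butterworth band-pass
#' 0.5-45 Hz, then resampling to 100 Hz (anti-aliased polyphase) when the
#' input rate is higher.
#'
#' @param eeg a [signal_trace()] with `fs >= 100` Hz.
#' @return A [signal_trace()] at 100 Hz.
#' @export
preprocess_eeg <- function(eeg) {
  stopifnot(inherits(eeg, "signal_trace"))
  if (eeg$fs < 100) stop("preprocess_eeg requires fs >= 100 Hz")
  x <- butter_filtfilt(eeg$samples, eeg$fs, 0.5, 45, order = 3)
  fs <- eeg$fs
  if (fs > 100) {
    if (fs != round(fs)) stop("resampling requires an integer input rate")
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(100L, as.integer(fs))
    x <- as.numeric(signal::resample(x, 100L / d, as.integer(fs) / d))
    fs <- 100
  }
  signal_trace(x, fs, eeg$label, eeg$t0)
}

#' Detect individual slow waves in preprocessed EEG
#'
#' The trace is filtered to 0.5-4 Hz (zero phase). Candidate waves are
#' spans between one downward zero crossing and the next that contain
#' exactly one negative phase followed by a positive phase. A candidate
#' becomes a slow wave when its negative-phase duration lies in
#' \[0.25, 1.25\] s and its trough magnitude reaches the 99th percentile
#' of the absolute filtered signal over the whole recording (a relative
#' criterion, so detection counts are invariant to amplitude rescaling).
#' The onset is the initial downward zero crossing (linearly interpolated
#' between samples) and the frequency is the inverse of the
#' onset-to-next-onset period.
#'
#' @param eeg a preprocessed [signal_trace()], at least 60 s long.
#' @param amp_percentile amplitude criterion percentile (default 0.99).
#' @param amp_mode "trough" applies the criterion to the trough magnitude
#'   (default); "peak2peak" to trough-to-peak range.
#' @param edge_margin events whose span lies within this many seconds of
#'   either record boundary are discarded (filter transients make edge
#'   candidates unreliable; default 2 s).
#' @return data.frame of class `slow_wave_events` with columns `onset`,
#'   `trough_time`, `trough_amp` (negative, uV), `neg_duration`,
#'   `end_time`, `frequency`; zero rows (with a message) if nothing
#'   qualifies. The amplitude threshold is kept as attribute
#'   `amp_threshold`.
#' @export
detect_slow_waves <- function(eeg, amp_percentile = 0.99,
                              amp_mode = c("trough", "peak2peak"),
                              edge_margin = 2) {
  stopifnot(inherits(eeg, "signal_trace"))
  amp_mode <- match.arg(amp_mode)
  fs <- eeg$fs
  if (length(eeg$samples) < 60 * fs)
    stop("detect_slow_waves requires >= 60 s of EEG")
  x <- butter_filtfilt(eeg$samples, fs, 0.5, 4, order = 3)
  thr <- quantile(abs(x), amp_percentile, names = FALSE)

  # downward zero crossings, with sub-sample linear interpolation
  dz <- which(x[-length(x)] >= 0 & x[-1] < 0)
  empty <- structure(
    data.frame(onset = numeric(0), trough_time = numeric(0),
               trough_amp = numeric(0), neg_duration = numeric(0),
               end_time = numeric(0), frequency = numeric(0)),
    class = c("slow_wave_events", "data.frame"), amp_threshold = thr)
  if (length(dz) < 2) {
    message("detect_slow_waves: no candidate waves")
    return(empty)
  }
  cross_t <- function(i) eeg$t0 + (i - 1 + x[i] / (x[i] - x[i + 1])) / fs

  out <- vector("list", length(dz) - 1L)
  for (k in seq_len(length(dz) - 1L)) {
    a <- dz[k]; b <- dz[k + 1]
    seg <- x[(a + 1):b]
    up <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)
    if (length(up) != 1L) next # not a single negative-then-positive cycle
    tr_rel <- which.min(seg[1:up])
    tr_amp <- seg[tr_rel]
    if (tr_amp >= 0) next
    pk_amp <- max(seg[(up + 1):length(seg)])
    if (pk_amp <= 0) next
    amp_stat <- if (amp_mode == "trough") -tr_amp else pk_amp - tr_amp
    if (amp_stat < thr) next
    onset <- cross_t(a)
    uz_idx <- a + up
    uz_t <- eeg$t0 + (uz_idx - 1 + x[uz_idx] / (x[uz_idx] - x[uz_idx + 1])) / fs
    neg_dur <- uz_t - onset
    if (neg_dur < 0.25 || neg_dur > 1.25) next
    end_t <- cross_t(b)
    if (onset < eeg$t0 + edge_margin ||
        end_t > trace_end(eeg) - edge_margin) next
    out[[k]] <- data.frame(
      onset = onset, trough_time = eeg$t0 + (a + tr_rel - 1) / fs,
      trough_amp = tr_amp, neg_duration = neg_dur, end_time = end_t,
      frequency = 1 / (end_t - onset))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    message("detect_slow_waves: no waves met the criteria")
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("slow_wave_events", "data.frame"),
            amp_threshold = thr)
}

#' Slow-wave activity (0.5-1.5 Hz band power) per segment
#'
#' Welch power of the preprocessed EEG integrated over 0.5-1.5 Hz in
#' non-overlapping segments.
#'
#' @param eeg a preprocessed [signal_trace()].
#' @param seg_len segment length, s (default 300).
#' @param t_start alignment of the first segment, s.
#' @return data.frame with columns `segment_start` and `swa_power`
#'   (uV^2).
#' @export
slow_wave_activity <- function(eeg, seg_len = 300, t_start = eeg$t0) {
  stopifnot(inherits(eeg, "signal_trace"))
  fs <- eeg$fs
  n_seg <- floor((length(eeg$samples) / fs - (t_start - eeg$t0)) / seg_len)
  out <- vector("list", max(n_seg, 0L))
  for (i in seq_len(n_seg)) {
    s <- t_start + (i - 1) * seg_len
    a <- round((s - eeg$t0) * fs) + 1L
    b <- min(a + seg_len * fs - 1L, length(eeg$samples))
    seg <- eeg$samples[a:b]
    ps <- welch_psd(seg, fs, nperseg = min(length(seg), 30 * fs))
    out[[i]] <- data.frame(
      segment_start = s,
      swa_power = band_power(ps$freq, ps$psd, 0.5, 1.5, right_closed = TRUE))
  }
  do.call(rbind, out)
}
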