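# Heart-rate variability metrics on 5-minute segments.
#
# Ectopic/artifact handling: RR intervals outside 0.24-6 s, or differing by
# more than 50% from the preceding interval, are excluded before any metric
# is computed.

rr_in_window <- function(beats, window) {
  t <- beats$r_times
  t <- t[t >= window[1] & t < window[2]]
  if (length(t) < 2) return(list(t = numeric(0), rr = numeric(0)))
  rr <- diff(t)
  ok <- rr > 0.24 & rr < 6
  if (length(rr) > 1)
    ok[-1] <- ok[-1] & abs(diff(rr)) <= 0.5 * head(rr, -1)
  list(t = t[-1][ok], rr = rr[ok])
}

#' Root-mean-square of successive RR differences
#'
#' Classic short-term (vagally mediated) heart-rate variability index:
#' `sqrt(mean(diff(RR)^2))` in milliseconds over the beats falling inside
#' the window.
#'
#' @param beats a [beat_series()].
#' @param window `c(start, end)` in seconds.
#' @return RMSSD in ms, or `NA` (with a message) if fewer than 3 beats
#'   fall in the window.
#' @export
rmssd <- function(beats, window) {
  stopifnot(inherits(beats, "beat_series"), length(window) == 2)
  w <- rr_in_window(beats, window)
  if (length(w$rr) < 2) {
    message("rmssd: insufficient beats in window [",
            window[1], ", ", window[2], ")")
    return(NA_real_)
  }
  sqrt(mean(diff(w$rr * 1000)^2))
}

#' Frequency-domain heart-rate variability
#'
#' The RR tachogram inside the window is interpolated to a uniform 4 Hz
#' grid (cubic spline), mean-detrended, and a Welch spectrum (128 s
#' segments, 50% overlap, Hann taper) is integrated by trapezoid over the
#' low-frequency band \[0.04, 0.15) Hz and high-frequency band
#' \[0.15, 0.4\] Hz.
#'
#' @param beats a [beat_series()].
#' @param window `c(start, end)` in seconds; at least 120 s with at least
#'   half the expected beats present.
#' @return List with `lf_power` and `hf_power` (ms^2), `lf_hf_ratio`
#'   (`NA` when HF power is zero), and `hf_peak_freq` (Hz, the spectral
#'   argmax inside the HF band).
#' @export
spectral_hrv <- function(beats, window) {
  stopifnot(inherits(beats, "beat_series"), length(window) == 2)
  span <- window[2] - window[1]
  if (span < 120) stop("spectral_hrv requires a window of at least 120 s")
  w <- rr_in_window(beats, window)
  empty <- list(lf_power = NA_real_, hf_power = NA_real_,
                lf_hf_ratio = NA_real_, hf_peak_freq = NA_real_)
  if (length(w$rr) < 4) return(empty)
  expected <- span / mean(w$rr)
  if (length(w$rr) < 0.5 * expected) {
    message("spectral_hrv: fewer than half the expected beats in window")
    return(empty)
  }
  fs_i <- 4
  grid <- seq(min(w$t), max(w$t), by = 1 / fs_i)
  if (length(grid) < 16) return(empty)
  tach <- spline(w$t, w$rr * 1000, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  ps <- welch_psd(tach, fs_i, nperseg = min(128 * fs_i, length(tach)))
  lf <- band_power(ps$freq, ps$psd, 0.04, 0.15)
  hf <- band_power(ps$freq, ps$psd, 0.15, 0.4, right_closed = TRUE)
  hf_sel <- ps$freq >= 0.15 & ps$freq <= 0.4
  hf_peak <- if (any(hf_sel) && hf > 0)
    ps$freq[hf_sel][which.max(ps$psd[hf_sel])] else NA_real_
  list(lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
       hf_peak_freq = hf_peak)
}

#' Heart-rate variability over non-overlapping 5-minute segments
#'
#' Segments are aligned to `t_start`; a partial trailing segment is
#' dropped.
#'
#' @param beats a [beat_series()].
#' @param seg_len segment length, s (default 300).
#' @param t_start,t_end analysis span; defaults to the full beat series.
#' @return data.frame with one row per segment: `segment_start`, `rmssd`
#'   (ms), `lf_power`, `hf_power` (ms^2), `lf_hf_ratio`, `hf_peak_freq`
#'   (Hz).
#' @export
hrv_segments <- function(beats, seg_len = 300, t_start = 0,
                         t_end = max(beats$r_times)) {
  n_seg <- floor((t_end - t_start) / seg_len)
  out <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    w <- t_start + c(i - 1, i) * seg_len
    sp <- if (seg_len >= 120) spectral_hrv(beats, w)
          else list(lf_power = NA_real_, hf_power = NA_real_,
                    lf_hf_ratio = NA_real_, hf_peak_freq = NA_real_)
    out[[i]] <- data.frame(segment_start = w[1],
                           rmssd = suppressMessages(rmssd(beats, w)),
                           lf_power = sp$lf_power, hf_power = sp$hf_power,
                           lf_hf_ratio = sp$lf_hf_ratio,
                           hf_peak_freq = sp$hf_peak_freq)
  }
  do.call(rbind, out)
}
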