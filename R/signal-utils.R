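#' Uniformly sampled physiological signal
#'
#' Light container for a single-channel trace (ECG or EEG): samples in
#' microvolts, sampling rate in Hz, a channel label, and the start time of
#' the first sample.
#'
#' @param samples numeric vector of amplitudes (uV); must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label channel name, e.g. "ECG".
#' @param t0 time of the first sample in seconds.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs, label = "signal", t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  structure(list(samples = as.numeric(samples), fs = fs,
                 label = label, t0 = t0),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s': %d samples @ %g Hz, %.1f s, t0 = %g s>\n",
              x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

trace_end <- function(trace) {
  trace$t0 + (length(trace$samples) - 1) / trace$fs
}

# Zero-phase Butterworth filtering (forward-backward, so the effective
# magnitude response is squared and phase is cancelled). The input is
# extended by odd reflection over about three periods of the lowest band
# edge before filtering, which suppresses the start/end transients a
# plain filtfilt leaves on finite records.
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 3) {
  nyq <- fs / 2
  if (!is.null(low) && !is.null(high)) {
    filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(low)) {
    filt <- signal::butter(order, low / nyq, type = "high")
  } else if (!is.null(high)) {
    filt <- signal::butter(order, high / nyq, type = "low")
  } else stop("need at least one band edge")
  n <- length(x)
  f_edge <- if (!is.null(low)) low else high / 10
  np <- min(n - 1L, as.integer(ceiling(3 * fs / f_edge)))
  if (np > 0L) {
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- as.numeric(signal::filtfilt(filt, c(pre, x, post)))
    y[(np + 1):(np + n)]
  } else as.numeric(signal::filtfilt(filt, x))
}

# Welch power spectral density with Hann taper and 50% overlap.
# Returns one-sided density in units^2/Hz so that sum(psd)*df approximates
# the variance of the input (Parseval check used in the tests).
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  u <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:nfreq])^2 / (fs * u)
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  list(freq = (0:(nfreq - 1)) * fs / nperseg, psd = psd * dbl)
}

# Integrated band power [lo, hi) (or closed on the right) by trapezoid rule.
band_power <- function(freq, psd, lo, hi, right_closed = FALSE) {
  sel <- if (right_closed) freq >= lo & freq <= hi else freq >= lo & freq < hi
  if (sum(sel) < 2L) return(0)
  pracma::trapz(freq[sel], psd[sel])
}

# Gaussian-shaped background noise with a 1/f^alpha amplitude spectrum,
# scaled to unit standard deviation before applying `scale`.
pink_noise <- function(n, alpha = 1, scale = 1) {
  white <- rnorm(n)
  xf <- fft(white)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index magnitude
  shape <- c(0, f[-1]^(-alpha / 2))
  y <- Re(fft(xf * shape, inverse = TRUE)) / n
  y <- y / sd(y)
  y * scale
}

#' Non-overlapping segment means
#'
#' Averages `values` over consecutive windows of `seg_len` seconds aligned
#' to `t_start`; the partial trailing segment is dropped. Used to build
#' the 5-minute segment series the dose-response statistics run on.
#'
#' @param times sample times, s.
#' @param values sample values.
#' @param seg_len segment length, s.
#' @param t_start,t_end analysis span.
#' @return data.frame with `segment_start`, `value` (mean; `NA` for empty
#'   segments) and `n`.
#' @export
segment_means <- function(times, values, seg_len = 300, t_start = 0,
                          t_end = max(times)) {
  n_seg <- floor((t_end - t_start) / seg_len)
  if (n_seg < 1L) return(data.frame(segment_start = numeric(0),
                                    value = numeric(0), n = integer(0)))
  starts <- t_start + seg_len * (seq_len(n_seg) - 1)
  out <- lapply(starts, function(s) {
    sel <- times >= s & times < s + seg_len
    data.frame(segment_start = s,
               value = if (any(sel)) mean(values[sel]) else NA_real_,
               n = sum(sel))
  })
  do.call(rbind, out)
}
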