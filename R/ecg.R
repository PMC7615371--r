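#' Detected heartbeat series
#'
#' R-peak times (strictly increasing, minimum 0.2 s refractory gap) with
#' the baseline-subtracted R-wave amplitude of each beat.
#'
#' @param r_times R-peak times, seconds.
#' @param r_amplitudes per-beat amplitudes, uV (same length).
#' @return Object of class `beat_series`.
#' @export
beat_series <- function(r_times, r_amplitudes = rep(NA_real_,
                                                    length(r_times))) {
  if (length(r_times) != length(r_amplitudes))
    stop("r_times and r_amplitudes must have equal length")
  if (length(r_times) > 1) {
    gaps <- diff(r_times)
    if (any(gaps <= 0)) stop("r_times must be strictly increasing")
    if (any(gaps < 0.2)) stop("successive beats closer than the 0.2 s refractory period")
  }
  structure(list(r_times = as.numeric(r_times),
                 r_amplitudes = as.numeric(r_amplitudes)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats", length(x$r_times)))
  if (length(x$r_times) > 1)
    cat(sprintf(", mean RR %.3f s", mean(diff(x$r_times))))
  cat(">\n")
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$r_times)

#' Detect R-peaks in a raw ECG trace
#'
#' Adaptive QRS detector in the Hamilton / Pan-Tompkins family: the ECG is
#' band-passed to 8-16 Hz (zero phase), a rectified-derivative envelope is
#' smoothed over 80 ms, and envelope peaks are classified against an
#' adaptive threshold that tracks running signal- and noise-peak
#' estimates. A 0.2 s refractory period is enforced and a search-back pass
#' with a halved threshold recovers beats whenever a gap exceeds 1.5x the
#' running RR mean. Each detection is refined to the local maximum of the
#' raw signal within +/-50 ms, and the amplitude is the raw value at the
#' refined peak minus a local baseline (median over the 100 ms window
#' ending 60 ms before the peak). Detection is invariant to amplitude
#' scaling and DC offset.
#'
#' @param ecg a [signal_trace()] with `fs >= 250` Hz and at least 10 s of
#'   data.
#' @return A [beat_series()]; empty (with a warning) for a flat trace.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "signal_trace"))
  fs <- ecg$fs
  x <- ecg$samples
  if (fs < 250) stop("detect_r_peaks requires fs >= 250 Hz")
  if (length(x) < 10 * fs) stop("detect_r_peaks requires >= 10 s of ECG")
  if (max(x) - min(x) < .Machine$double.eps * 100) {
    warning("flat ECG signal: no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }

  bp <- butter_filtfilt(x - mean(x), fs, 8, 16)
  env <- abs(c(diff(bp), 0))
  k <- max(1L, round(0.08 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0

  # local maxima of the envelope
  pk <- which(diff(sign(diff(env))) < 0) + 1L
  if (!length(pk)) {
    warning("no envelope peaks: no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }
  pk_t <- (pk - 1) / fs
  pk_v <- env[pk]

  init <- pk_v[pk_t <= 10]
  spk <- if (length(init)) max(init) * 0.7 else max(pk_v) * 0.7
  npk <- if (length(init)) median(init) * 0.5 else 0
  refract <- 0.2
  accepted <- integer(0)
  rejected <- integer(0)
  last_t <- -Inf
  prev_t <- -Inf # acceptance before the last (for refractory replacement)
  rr_hist <- numeric(0)

  for (j in seq_along(pk)) {
    thr <- npk + 0.3125 * (spk - npk)
    rr_mean <- if (length(rr_hist)) mean(tail(rr_hist, 8)) else 1
    # search-back: long gap since the last accepted beat
    if (is.finite(last_t) && (pk_t[j] - last_t) > 1.5 * rr_mean &&
        length(rejected)) {
      cand <- rejected[pk_t[rejected] > last_t + refract &
                         pk_t[rejected] < pk_t[j] - refract]
      if (length(cand)) {
        best <- cand[which.max(pk_v[cand])]
        if (pk_v[best] >= 0.5 * thr) {
          accepted <- c(accepted, best)
          rr_hist <- c(rr_hist, pk_t[best] - last_t)
          prev_t <- last_t
          last_t <- pk_t[best]
          spk <- 0.25 * pk_v[best] + 0.75 * spk
          rejected <- rejected[pk_t[rejected] > last_t]
        }
      }
    }
    if (pk_t[j] - last_t < refract) {
      # a taller envelope peak inside the refractory window supersedes the
      # previous acceptance (e.g. a P bump accepted just before its R)
      if (length(accepted) && pk_v[j] > pk_v[accepted[length(accepted)]]) {
        accepted[length(accepted)] <- j
        last_t <- pk_t[j]
        if (length(rr_hist)) rr_hist[length(rr_hist)] <- pk_t[j] - prev_t
        spk <- 0.125 * pk_v[j] + 0.875 * spk
      }
      next
    }
    if (pk_v[j] >= thr) {
      if (is.finite(last_t)) rr_hist <- c(rr_hist, pk_t[j] - last_t)
      accepted <- c(accepted, j)
      prev_t <- last_t
      last_t <- pk_t[j]
      spk <- 0.125 * pk_v[j] + 0.875 * spk
    } else {
      rejected <- c(rejected, j)
      npk <- 0.125 * pk_v[j] + 0.875 * npk
    }
  }
  if (!length(accepted)) {
    warning("no beats passed the adaptive threshold")
    return(beat_series(numeric(0), numeric(0)))
  }

  # refine to the raw-signal maximum within +/-50 ms
  half <- round(0.05 * fs)
  idx <- sort(pk[accepted])
  ref <- vapply(idx, function(i) {
    a <- max(1L, i - half); b <- min(length(x), i + half)
    as.integer(a + which.max(x[a:b]) - 1L)
  }, 1L)
  ref <- sort(unique(ref))
  # enforce refractory on refined times, keeping the taller peak
  if (length(ref) > 1) {
    keep <- rep(TRUE, length(ref))
    last <- 1L
    for (i in 2:length(ref)) {
      if ((ref[i] - ref[last]) / fs < refract) {
        if (x[ref[i]] > x[ref[last]]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    ref <- ref[keep]
  }
  amp <- vapply(ref, function(i) {
    a <- i - round(0.16 * fs); b <- i - round(0.06 * fs)
    base <- if (a >= 1) median(x[a:b]) else 0
    x[i] - base
  }, 1)
  beat_series(ecg$t0 + (ref - 1) / fs, amp)
}

#' Instantaneous heart rate from detected beats
#'
#' Each RR interval yields one sample `60 / RR` bpm, placed at the
#' midpoint of the interval.
#'
#' @param beats a [beat_series()] with at least 2 beats.
#' @return data.frame of class `heart_rate_series` with columns `time_s`
#'   and `hr_bpm`.
#' @export
heart_rate <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$r_times) < 2) stop("heart_rate requires >= 2 beats")
  rr <- diff(beats$r_times)
  out <- data.frame(time_s = head(beats$r_times, -1) + rr / 2,
                    hr_bpm = 60 / rr)
  class(out) <- c("heart_rate_series", "data.frame")
  out
}

#' Average ECG beat template
#'
#' Mean raw waveform over the window \[-0.2, +0.4\] s around each R-peak;
#' beats whose window exceeds the trace are skipped.
#'
#' @param ecg the raw [signal_trace()].
#' @param beats a [beat_series()]; at least 10 usable beats required.
#' @return List of class `ecg_template`: `lag` (s), `mean` (uV),
#'   `n_beats`.
#' @export
beat_template <- function(ecg, beats) {
  stopifnot(inherits(ecg, "signal_trace"), inherits(beats, "beat_series"))
  fs <- ecg$fs
  pre <- round(0.2 * fs); post <- round(0.4 * fs)
  centers <- round((beats$r_times - ecg$t0) * fs) + 1L
  ok <- centers - pre >= 1L & centers + post <= length(ecg$samples)
  centers <- centers[ok]
  if (length(centers) < 10)
    stop("beat_template requires >= 10 beats fully inside the trace")
  mat <- vapply(centers,
                function(c0) ecg$samples[(c0 - pre):(c0 + post)],
                numeric(pre + post + 1))
  structure(list(lag = (-pre:post) / fs, mean = rowMeans(mat),
                 n_beats = length(centers)),
            class = "ecg_template")
}

#' @export
print.ecg_template <- function(x, ...) {
  cat(sprintf("<ecg_template: %d beats, peak %.0f uV at lag %.3f s>\n",
              x$n_beats, max(x$mean), x$lag[which.max(x$mean)]))
  invisible(x)
}

#' Match detected beats against ground truth
#'
#' Greedy one-to-one matching within a tolerance; used to score detector
#' recall and precision on simulated recordings.
#'
#' @param detected,truth beat time vectors (s).
#' @param tol matching tolerance, s.
#' @return List with `recall`, `precision`, `n_matched`.
#' @export
match_beats <- function(detected, truth, tol = 0.01) {
  if (!length(truth)) return(list(recall = NA_real_,
                                  precision = NA_real_, n_matched = 0L))
  used <- rep(FALSE, length(detected))
  hit <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      hit <- hit + 1L
      used[j] <- TRUE
    }
  }
  list(recall = hit / length(truth),
       precision = if (length(detected)) hit / length(detected) else NA_real_,
       n_matched = hit)
}
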