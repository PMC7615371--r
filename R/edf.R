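# Minimal EDF (European Data Format) writer/reader for the recordings this
# package produces. EDF stores an ASCII header followed by 1-second data
# records of 16-bit little-endian integers per channel; channels may have
# different sampling rates. Only the subset of the format needed here is
# supported (no annotations, no EDF+).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width) # left-justified, space padded
}

#' Write signal traces to an EDF file
#'
#' Writes one or more [signal_trace()] channels as a single EDF file with
#' 1-second data records. Traces are truncated to a whole number of seconds
#' (the longest common duration is used). Physical scaling is chosen per
#' channel from the data range, so quantization error is at most
#' (range / 65535) / 2.
#'
#' @param traces a list of `signal_trace` objects (e.g. `list(ECG = ..,
#'   EEG = ..)`); names override the trace labels if given.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  labels <- names(traces)
  if (is.null(labels)) labels <- vapply(traces, `[[`, "", "label")
  ns <- length(traces)
  fs <- vapply(traces, `[[`, 1, "fs")
  if (any(fs != round(fs))) stop("EDF writer requires integer sampling rates")
  n_rec <- min(vapply(traces, function(tr) floor(length(tr$samples) / tr$fs),
                      1))
  if (n_rec < 1) stop("traces shorter than one second")
  phys_min <- phys_max <- dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- traces[[i]]$samples[seq_len(n_rec * fs[i])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-9) { hi <- lo + 1 }
    phys_min[[i]] <- lo; phys_max[[i]] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 8))
  field <- function(f, width) paste0(vapply(f, edf_pad, "", width),
                                     collapse = "")
  hdr <- paste0(hdr,
    field(labels, 16), field(rep("", ns), 80), field(rep("uV", ns), 8),
    field(sprintf("%.6g", unlist(phys_min)), 8),
    field(sprintf("%.6g", unlist(phys_max)), 8),
    field(rep(-32768, ns), 8), field(rep(32767, ns), 8),
    field(rep("", ns), 80), field(fs, 8), field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the header and data records of a plain EDF file and returns the
#' channels as [signal_trace()] objects with physical (uV) values.
#'
#' @param path EDF file path.
#' @return Named list of `signal_trace` objects.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(8))
  rdn <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdn(16); rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8)); phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8)); dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8)) # samples per record
  rdn(32)
  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      x <- (d - dig_min[i]) / (dig_max[i] - dig_min[i]) *
        (phys_max[i] - phys_min[i]) + phys_min[i]
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- x
    }
  }
  names(out) <- labels
  lapply(seq_len(ns), function(i)
    signal_trace(out[[i]], fs = spr[i] / rec_dur, label = labels[i])) |>
    setNames(labels)
}
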