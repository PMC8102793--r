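#' Write a continuous multichannel recording as EDF
#'
#' Minimal European Data Format writer: one file, 16-bit samples, 1 s data
#' records, physical units microvolts. Each channel is scaled independently
#' to its own physical range, so the quantization step is
#' `range / 65535` per channel. The final record is zero-padded when the
#' recording length is not a whole number of seconds.
#'
#' @param signals Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (samples per 1 s record).
#' @param channel_labels Character vector of channel labels.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(signals, sampling_rate, channel_labels, path) {
  stopifnot(is.matrix(signals), nrow(signals) == length(channel_labels))
  ns <- nrow(signals)
  spr <- as.integer(round(sampling_rate))
  n_samp <- ncol(signals)
  n_rec <- ceiling(n_samp / spr)

  pmin_ <- apply(signals, 1, min)
  pmax_ <- apply(signals, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # scale with the same (text-rounded) ranges the header stores, so the
  # reader reconstructs with identical constants
  pmin_ <- as.numeric(sprintf("%.6g", pmin_))
  pmax_ <- as.numeric(sprintf("%.6g", pmax_))
  dmin <- -32768L; dmax <- 32767L

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(channel_labels, pad, "", w = 16),
    rep(pad("", 80), ns),
    rep(pad("uV", 8), ns),
    vapply(sprintf("%.6g", pmin_), pad, "", w = 8),
    vapply(sprintf("%.6g", pmax_), pad, "", w = 8),
    rep(pad(dmin, 8), ns),
    rep(pad(dmax, 8), ns),
    rep(pad("", 80), ns),
    rep(pad(spr, 8), ns),
    rep(pad("", 32), ns)
  )
  writeChar(paste0(fields, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- matrix(0, ns, n_rec * spr)
  padded[, seq_len(n_samp)] <- signals
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      d <- round((padded[i, idx] - pmin_[i]) * scale[i]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]: reads the header and all 16-bit data
#' records and rescales to physical units. Assumes a common sampling rate
#' across channels.
#'
#' @param path EDF file path.
#' @return List with `signals` (channels x samples matrix, possibly
#'   zero-padded to whole records), `sampling_rate`, `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)        # transducer
  for (i in seq_len(ns)) rd(8)         # physical dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)        # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  signals <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      signals[i, idx] <- pmin_[i] +
        (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    }
  }
  list(signals = signals, sampling_rate = spr[1] / rec_dur,
       channel_labels = labels)
}
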