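#' Band-limit a continuous recording
#'
#' Zero-phase high-pass + low-pass filtering: a 4th-order Butterworth per
#' pass, applied forward and backward with [signal::filtfilt()] so the
#' effective response is 8th order with no phase distortion. Channels are
#' de-meaned after filtering (the high-pass removes DC up to transients).
#'
#' @param signals Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param hp High-pass cutoff in Hz (default 0.5).
#' @param lp Low-pass cutoff in Hz (default 30).
#' @return Filtered matrix of identical shape.
#' @export
bandlimit <- function(signals, sampling_rate, hp = 0.5, lp = 30) {
  if (!(hp > 0 && hp < lp && lp < sampling_rate / 2)) {
    stop("need 0 < hp < lp < sampling_rate/2", call. = FALSE)
  }
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  bh <- signal::butter(4, hp / (sampling_rate / 2), type = "high")
  bl <- signal::butter(4, lp / (sampling_rate / 2), type = "low")
  x <- t(signals)                        # samples x channels
  x <- filtfilt_mat(x, bh$b, bh$a, pad = min(nrow(x) - 1L,
                                             round(2 * sampling_rate)))
  x <- sweep(x, 2, colMeans(x))
  x <- filtfilt_mat(x, bl$b, bl$a, pad = min(nrow(x) - 1L,
                                             round(2 * sampling_rate)))
  t(x)
}

# causal IIR (direct form) applied column-wise in C via stats::filter;
# ts class stripped to avoid dispatch copies on large matrices
iir_mat <- function(x, b, a) {
  v <- stats::filter(x, b / a[1], method = "convolution", sides = 1)
  v <- matrix(as.numeric(v), nrow(x), ncol(x))
  # convolution leaves the first length(b)-1 rows NA: fill partial sums
  for (i in seq_len(length(b) - 1)) {
    j <- seq_len(i)
    v[i, ] <- colSums(matrix(b[j] / a[1], ncol = ncol(x),
                             nrow = i) * x[rev(j), , drop = FALSE])
  }
  r <- stats::filter(v, -a[-1] / a[1], method = "recursive")
  matrix(as.numeric(r), nrow(x), ncol(x))
}

# zero-phase forward-backward filtering with odd-reflection edge padding
filtfilt_mat <- function(x, b, a, pad) {
  n <- nrow(x)
  if (pad > 0) {
    top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
      x[(pad + 1):2, , drop = FALSE]
    bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
      x[(n - 1):(n - pad), , drop = FALSE]
    x <- rbind(top, x, bot)
  }
  y <- iir_mat(x, b, a)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_mat(y, b, a)
  y <- y[nrow(y):1, , drop = FALSE]
  if (pad > 0) y <- y[(pad + 1):(pad + n), , drop = FALSE]
  y
}

#' Segment a continuous recording into trial epochs
#'
#' Cuts one epoch per trial onset spanning `span` seconds around it
#' (default `[-2.0, 5.5)`, i.e. 7.5 s including the full 5.5 s trial and a
#' 2 s pre-onset buffer; consecutive epochs of a 5.5 s-spaced session
#' therefore overlap by 2 s). Onsets whose epoch would extend past either
#' recording edge are dropped with a warning and recorded in the returned
#' metadata attribute.
#'
#' @param session An `eeg_session` (or a list with `signals`,
#'   `sampling_rate`, `channel_labels`, `channel_roles`, `events`).
#' @param span Two-element numeric, seconds relative to onset.
#' @return An [epoch_set()]; attribute `"dropped"` lists dropped trials.
#' @export
segment_epochs <- function(session, span = c(-2.0, 5.5)) {
  fs <- session$sampling_rate
  n_span <- round((span[2] - span[1]) * fs)
  n_total <- ncol(session$signals)
  onsets <- session$events$onset
  start_idx <- round((onsets + span[1]) * fs) + 1L
  ok <- start_idx >= 1L & (start_idx + n_span - 1L) <= n_total
  if (any(!ok)) {
    warning(sprintf("dropped %d trial(s) too close to the recording edge",
                    sum(!ok)), call. = FALSE)
  }
  meta <- session$events[ok, , drop = FALSE]
  data <- array(0, dim = c(sum(ok), nrow(session$signals), n_span))
  kept <- which(ok)
  for (j in seq_along(kept)) {
    idx <- start_idx[kept[j]] + 0:(n_span - 1L)
    data[j, , ] <- session$signals[, idx]
  }
  es <- epoch_set(data, fs, session$channel_labels, session$channel_roles,
                  time_axis = span[1] + (0:(n_span - 1L)) / fs,
                  trial_meta = meta)
  attr(es, "dropped") <- session$events$trial[!ok]
  es
}

#' Reject trials with ocular artifacts
#'
#' Removes any trial whose peak-to-peak voltage over the full epoch in ANY
#' EOG channel strictly exceeds `threshold` (default 18.75 uV). "Voltage
#' shift" is operationalized as within-epoch max minus min. Applied after
#' band-limiting; a trial at exactly the threshold is retained.
#'
#' @param epochs An [epoch_set()] containing at least one EOG channel.
#' @param threshold Peak-to-peak rejection threshold in microvolts.
#' @return The retained `epoch_set`; attribute `"rejection_log"` is a
#'   tibble of per-trial peak-to-peak values and decisions.
#' @export
reject_eog_trials <- function(epochs, threshold = 18.75) {
  eog <- eog_index(epochs)
  if (!length(eog)) {
    stop("no EOG channels present: cannot screen ocular artifacts",
         call. = FALSE)
  }
  ptp <- apply(epochs$data[, eog, , drop = FALSE], 1, function(m) {
    max(apply(matrix(m, nrow = length(eog)), 1,
              function(x) max(x) - min(x)))
  })
  keep <- !(ptp > threshold)
  out <- subset_trials(epochs, keep)
  attr(out, "rejection_log") <- tibble::tibble(
    trial = epochs$trial_meta$trial, eog_ptp = ptp, rejected = !keep,
    threshold = threshold
  )
  out
}

#' Reject trials with extreme voltage spikes
#'
#' Removes trials whose scalp-channel peak absolute voltage exceeds
#' `factor` times the median of the per-trial peak absolute voltages
#' ("an order of magnitude" rule, default factor 10). Skipped with a
#' warning when fewer than 3 trials remain (the median is unstable).
#'
#' @param epochs An [epoch_set()].
#' @param factor Multiplier over the median per-trial peak (> 1); `Inf`
#'   disables the screen.
#' @return The retained `epoch_set`; attribute `"rejection_log"` records
#'   peaks and decisions.
#' @export
reject_spike_trials <- function(epochs, factor = 10) {
  stopifnot(factor > 1)
  sc <- scalp_index(epochs)
  if (n_trials(epochs) < 3) {
    warning("fewer than 3 trials: spike screening skipped", call. = FALSE)
    return(epochs)
  }
  peaks <- apply(epochs$data[, sc, , drop = FALSE], 1,
                 function(m) max(abs(m)))
  keep <- peaks <= factor * stats::median(peaks)
  out <- subset_trials(epochs, keep)
  attr(out, "rejection_log") <- tibble::tibble(
    trial = epochs$trial_meta$trial, peak_abs = peaks, rejected = !keep,
    factor = factor
  )
  out
}

#' Partition correct trials by task type
#'
#' Keeps only correct trials and splits them over the four task types.
#' Task types with zero correct trials yield an empty epoch set and are
#' flagged; downstream PAF for such a cell is reported missing.
#'
#' @param epochs An [epoch_set()] whose `trial_meta` has `task_type` and
#'   `correct`.
#' @return Named list of `epoch_set`s (`2P`, `2R`, `3P`, `3R`); attribute
#'   `"counts"` tabulates retained trials, attribute `"empty"` names task
#'   types with no correct trials.
#' @export
split_correct_trials <- function(epochs) {
  stopifnot(all(c("task_type", "correct") %in% names(epochs$trial_meta)))
  out <- purrr::map(stats::setNames(task_types(), task_types()), function(tt) {
    subset_trials(epochs, epochs$trial_meta$correct &
                    epochs$trial_meta$task_type == tt)
  })
  counts <- vapply(out, n_trials, 0L)
  attr(out, "counts") <- counts
  attr(out, "empty") <- names(counts)[counts == 0]
  out
}

#' Preprocess one session into analysis-ready epochs
#'
#' Fixed pipeline order: band-limit the continuous recording, segment into
#' 7.5 s epochs, (optional external ICA hook), EOG artifact rejection,
#' spike rejection. Rejections only drop trials; retained voltages are
#' never modified.
#'
#' @param session An `eeg_session`.
#' @param hp,lp Band-limit cutoffs (Hz). @param eog_threshold Peak-to-peak
#'   EOG rejection threshold (uV). @param spike_factor Spike screen factor.
#' @param span Epoch span (s) around trial onset.
#' @param ica_hook Optional function `epoch_set -> epoch_set` applied after
#'   segmentation (e.g. an external ICA cleaner); `NULL` to skip.
#' @return An [epoch_set()] of screened trials.
#' @export
preprocess_session <- function(session, hp = 0.5, lp = 30,
                               eog_threshold = 18.75, spike_factor = 10,
                               span = c(-2.0, 5.5), ica_hook = NULL) {
  filt <- bandlimit(session$signals, session$sampling_rate, hp, lp)
  ses <- session
  ses$signals <- filt
  epochs <- segment_epochs(ses, span)
  if (!is.null(ica_hook)) epochs <- ica_hook(epochs)
  epochs <- reject_eog_trials(epochs, eog_threshold)
  reject_spike_trials(epochs, spike_factor)
}
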