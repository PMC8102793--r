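#' Proportional channel weights from band power
#'
#' The center-of-gravity weighting step: channel power (already summed over
#' the alpha band) at a single time point is turned into weights as each
#' channel's proportional share of the total. If every channel has zero
#' power at that time point the weights degenerate to uniform (with a
#' warning), keeping downstream averages defined.
#'
#' @param power_at_t Non-negative numeric vector, one band-summed power per
#'   channel.
#' @return Numeric weights summing to 1, same order as the input.
#' @export
channel_weights <- function(power_at_t) {
  if (any(power_at_t < 0)) stop("power must be non-negative", call. = FALSE)
  tot <- sum(power_at_t)
  if (tot == 0) {
    warning("all-zero channel power at a time point: uniform weights used",
            call. = FALSE)
    return(rep(1 / length(power_at_t), length(power_at_t)))
  }
  power_at_t / tot
}

#' Channel-weighted alpha-band power
#'
#' For each time point, weights are recomputed from the posterior channels'
#' power summed over the alpha band, then for every band frequency the
#' per-channel power vector is multiplied by the weight vector and averaged
#' over channels. The result is a frequencies x times matrix whose
#' frequency profile emphasizes channels with strong alpha. Weights are
#' scale-free, so rescaling all channels by a common factor rescales the
#' output without moving its peak.
#'
#' @param tfr A `tfr` from [tfr_transform()].
#' @param posterior_channels Channel labels to weight over (the posterior
#'   subset).
#' @param band Alpha band bounds in Hz (inclusive, default `c(8, 14)`).
#' @return Matrix `n_band_freqs x n_times` with attribute `"freqs"` (the
#'   band frequency grid) and `"degenerate_times"` (indices of all-zero
#'   time points).
#' @export
weighted_alpha_power <- function(tfr, posterior_channels, band = c(8, 14)) {
  if (length(posterior_channels) < 1) {
    stop("empty posterior channel selection", call. = FALSE)
  }
  ch <- match(posterior_channels, tfr$channel_labels)
  if (anyNA(ch)) stop("posterior channels missing from TFR", call. = FALSE)
  fsel <- which(tfr$freq_axis >= band[1] - 1e-9 &
                  tfr$freq_axis <= band[2] + 1e-9)
  p <- tfr$power[ch, fsel, , drop = FALSE]   # ch x f x t
  band_sum <- apply(p, c(1, 3), sum)         # ch x t
  tot <- colSums(band_sum)
  w <- sweep(band_sum, 2, tot, "/")          # ch x t
  degen <- which(tot == 0)
  if (length(degen)) {
    warning(sprintf("%d time point(s) with all-zero band power: uniform weights",
                    length(degen)), call. = FALSE)
    w[, degen] <- 1 / length(ch)
  }
  nf <- length(fsel); nt <- dim(p)[3]
  out <- matrix(0, nf, nt)
  for (f in seq_len(nf)) {
    out[f, ] <- colMeans(matrix(p[, f, ], nrow = length(ch)) * w)
  }
  attr(out, "freqs") <- tfr$freq_axis[fsel]
  attr(out, "times") <- tfr$time_axis
  attr(out, "degenerate_times") <- degen
  out
}

#' Extract the peak alpha frequency over an analysis window
#'
#' Averages the weighted alpha-power matrix over the time points whose
#' window centers fall in the half-open span, then takes the frequency of
#' the maximum. Exact ties are broken toward the lowest frequency and
#' flagged via the `"tie"` attribute.
#'
#' @param weighted Output of [weighted_alpha_power()].
#' @param span Two-element numeric `c(start, end)` in seconds, half-open
#'   `[start, end)`; or a name from [analysis_windows()].
#' @return PAF in Hz (on the grid), with attribute `"tie"` (logical).
#' @export
extract_paf <- function(weighted, span) {
  if (is.character(span)) span <- analysis_windows()[[span]]
  times <- attr(weighted, "times")
  freqs <- attr(weighted, "freqs")
  sel <- times >= span[1] - 1e-9 & times < span[2] - 1e-9
  if (!any(sel)) stop("analysis window contains no time points", call. = FALSE)
  prof <- rowMeans(weighted[, sel, drop = FALSE])
  i <- which.max(prof)                        # ties -> lowest frequency
  paf <- freqs[i]
  attr(paf, "tie") <- sum(prof == prof[i]) > 1
  paf
}

#' PAF modulation
#'
#' Signed change of peak alpha frequency from baseline to maintenance:
#' `maintenance - baseline`, in Hz.
#'
#' @param paf_maintenance,paf_baseline PAF estimates in Hz.
#' @return Modulation in Hz.
#' @export
paf_modulation <- function(paf_maintenance, paf_baseline) {
  as.numeric(paf_maintenance) - as.numeric(paf_baseline)
}

#' PAF records for one subject's epochs
#'
#' Runs the spectral + weighting + peak-extraction chain on correct trials:
#' per task type (induced power averaged over that task type's correct
#' trials) and pooled over all correct trials. For each, PAF is extracted
#' in the baseline, maintenance and pre-test-task windows and modulation is
#' the maintenance - baseline difference. Task types without correct
#' trials yield `NA` PAF.
#'
#' @param epochs A preprocessed [epoch_set()] with behavioral metadata.
#' @param posterior_channels Posterior channel labels.
#' @param band Alpha band (Hz). @param window,stride,freqs Passed to
#'   [tfr_transform()].
#' @param by_task Also compute per-task-type records (default TRUE).
#' @param tlim Time range of TFR window centers (default covers the
#'   analysis windows with a small margin).
#' @return Tibble: `task_type` (`"all"` for pooled), `window`, `paf`,
#'   `modulation` (on baseline rows `NA`; reported on maintenance rows),
#'   `n_trials`.
#' @export
subject_paf <- function(epochs, posterior_channels, band = c(8, 14),
                        window = 2.0, stride = 0.05,
                        freqs = seq(2, 20, by = 0.5), by_task = TRUE,
                        tlim = NULL) {
  if (is.null(tlim)) {
    spans <- unlist(analysis_windows())
    tlim <- c(min(spans), max(spans))
  }
  sets <- list(all = subset_trials(epochs, epochs$trial_meta$correct))
  if (by_task) sets <- c(sets, split_correct_trials(epochs))
  wins <- analysis_windows()
  purrr::imap_dfr(sets, function(es, nm) {
    if (n_trials(es) == 0) {
      return(tibble::tibble(task_type = nm, window = names(wins),
                            paf = NA_real_, modulation = NA_real_,
                            n_trials = 0L))
    }
    tfr <- tfr_transform(es, window = window, stride = stride, freqs = freqs,
                         channels = posterior_channels, tlim = tlim)
    wap <- weighted_alpha_power(tfr, posterior_channels, band)
    pafs <- vapply(wins, function(sp) as.numeric(extract_paf(wap, sp)), 0)
    tibble::tibble(
      task_type = nm, window = names(wins), paf = as.numeric(pafs),
      modulation = ifelse(names(wins) == "maintenance",
                          paf_modulation(pafs[["maintenance"]],
                                         pafs[["baseline"]]), NA_real_),
      n_trials = n_trials(es)
    )
  })
}
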