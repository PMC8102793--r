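#' Construct an epoch set
#'
#' Container for segmented EEG: a trials x channels x samples voltage array
#' (microvolts) with its sampling rate, channel roles, time axis relative to
#' trial onset, and per-trial metadata.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one per channel.
#' @param channel_roles Named character vector mapping each label to one of
#'   `"scalp"`, `"posterior"`, `"eog"`. Posterior channels are scalp
#'   channels flagged for PAF analysis; EOG channels are excluded from all
#'   spectral analysis.
#' @param time_axis Numeric vector of sample times (s) relative to trial
#'   onset; length must equal `dim(data)[3]`.
#' @param trial_meta Tibble with one row per trial; expected columns include
#'   `task_type` (one of 2P, 2R, 3P, 3R), `correct` (logical) and `rt` (ms)
#'   when behavioral data exist.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, channel_labels, channel_roles,
                      time_axis, trial_meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  if (dim(data)[2] != length(channel_labels)) {
    stop("channel_labels length must match dim(data)[2]", call. = FALSE)
  }
  if (dim(data)[3] != length(time_axis)) {
    stop("time_axis length must match dim(data)[3]", call. = FALSE)
  }
  if (!all(channel_labels %in% names(channel_roles))) {
    stop("every channel label needs a role", call. = FALSE)
  }
  roles <- channel_roles[channel_labels]
  if (!all(roles %in% c("scalp", "posterior", "eog"))) {
    stop("channel roles must be scalp, posterior or eog", call. = FALSE)
  }
  if (is.null(trial_meta)) {
    trial_meta <- tibble::tibble(trial = seq_len(n_trials))
  }
  if (nrow(trial_meta) != n_trials) {
    stop("trial_meta must have one row per trial", call. = FALSE)
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, channel_roles = roles,
         time_axis = time_axis, trial_meta = tibble::as_tibble(trial_meta)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time %g to %g s; %d posterior, %d EOG channels\n",
              min(x$time_axis), max(x$time_axis),
              sum(x$channel_roles == "posterior"),
              sum(x$channel_roles == "eog")))
  if ("task_type" %in% names(x$trial_meta)) {
    tab <- table(x$trial_meta$task_type)
    cat("  trials by task type:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Keep a subset of trials
#'
#' Pure selection along the trial axis: retained voltage data are untouched.
#'
#' @param epochs An [epoch_set()].
#' @param keep Logical or integer index over trials.
#' @return An `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[keep, , , drop = FALSE],
            epochs$sampling_rate, epochs$channel_labels,
            epochs$channel_roles, epochs$time_axis,
            epochs$trial_meta[keep, , drop = FALSE])
}

n_trials <- function(epochs) dim(epochs$data)[1]

scalp_index <- function(epochs) which(epochs$channel_roles != "eog")
eog_index <- function(epochs) which(epochs$channel_roles == "eog")
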