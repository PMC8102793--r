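#' Simulation configuration for a synthetic working-memory EEG cohort
#'
#' Builds and validates the parameter set that drives [simulate_subject()]
#' and [simulate_cohort()]. Defaults describe a cohort of the kind the
#' pipeline targets: a 512 Hz, 47-channel scalp montage (plus two EOG
#' channels) with a 14-channel posterior subset, eight 64-trial blocks of a
#' four-condition visuospatial working-memory task, posterior alpha
#' oscillations riding on a 1/f aperiodic background, and sex-specific
#' baseline-to-maintenance shifts of the peak alpha frequency (PAF).
#'
#' Frequencies are in Hz, amplitudes in microvolts, durations in seconds.
#' `modulation_mean_f`/`modulation_mean_m` are the group means of the
#' within-subject PAF shift (maintenance minus baseline); the defaults
#' (+0.30 Hz for females, 0.00 Hz for males, SDs 1.1 / 0.7 Hz) give females
#' the larger and more variable modulation.
#'
#' @param n_females,n_males Number of subjects per sex group.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_blocks,trials_per_block Task structure; trials are
#'   pseudorandomized over the four task types within each block.
#' @param n_channels Number of scalp channels (labelled `ch01`, `ch02`, ...).
#'   Two EOG channels (`EOG1`, `EOG2`) are always appended.
#' @param posterior_channels Labels of the posterior scalp subset used for
#'   PAF estimation. Must be a subset of the scalp labels.
#' @param baseline_paf_mean,baseline_paf_sd Population distribution of the
#'   subject baseline PAF (Hz).
#' @param modulation_mean_f,modulation_sd_f,modulation_mean_m,modulation_sd_m
#'   Group distributions of the PAF modulation (Hz).
#' @param aperiodic_exponent Exponent chi of the 1/f^chi background.
#' @param alpha_amplitude Peak amplitude of the posterior alpha oscillation
#'   (uV). @param noise_amplitude RMS amplitude of the aperiodic background
#'   (uV).
#' @param blink_rate Per-trial probability of a blink transient in the EOG
#'   channels. @param blink_amplitude Blink peak amplitude (uV).
#' @param paf_accuracy_r_male_relative Subject-level Gaussian-copula
#'   correlation, in males, between baseline PAF and accuracy on
#'   Relative task types.
#' @param accuracy_means Named vector of mean proportion correct per task
#'   type (`2P`, `2R`, `3P`, `3R`).
#' @param rt_means Named vector of mean response times (ms) per task type.
#' @param accuracy_logit_sd SD of the subject random effect on the logit
#'   accuracy scale. @param rt_sd Between-subject SD of log-normal response
#'   times (ms, approximate).
#' @param paf_trial_sd Within-subject trial-to-trial SD of the injected
#'   alpha frequency (Hz); 0 keeps the frequency fixed per window.
#' @param seed Integer seed; the same config reproduces the same cohort.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_females = 2, n_males = 1, n_blocks = 1,
#'                   trials_per_block = 8, n_channels = 14,
#'                   posterior_channels = sprintf("ch%02d", 1:14), seed = 1)
#' cfg$n_trials
#' @export
sim_config <- function(n_females = 77,
                       n_males = 33,
                       sampling_rate = 512,
                       n_blocks = 8,
                       trials_per_block = 64,
                       n_channels = 47,
                       posterior_channels = sprintf("ch%02d", 34:47),
                       baseline_paf_mean = 10.4,
                       baseline_paf_sd = 1.2,
                       modulation_mean_f = 0.30,
                       modulation_sd_f = 1.1,
                       modulation_mean_m = 0.00,
                       modulation_sd_m = 0.7,
                       aperiodic_exponent = 1.0,
                       alpha_amplitude = 10,
                       noise_amplitude = 2,
                       blink_rate = 0.1,
                       blink_amplitude = 100,
                       paf_accuracy_r_male_relative = 0.4,
                       accuracy_means = c(`2P` = 0.915, `2R` = 0.925,
                                          `3P` = 0.710, `3R` = 0.860),
                       rt_means = c(`2P` = 654, `2R` = 698,
                                    `3P` = 736, `3R` = 833),
                       accuracy_logit_sd = 0.55,
                       rt_sd = 120,
                       paf_trial_sd = 0,
                       seed = 1L) {
  counts <- c(n_females = n_females, n_males = n_males, n_blocks = n_blocks,
              trials_per_block = trials_per_block, n_channels = n_channels)
  if (any(counts != round(counts)) || any(counts <= 0)) {
    stop("invalid config: counts must be positive integers", call. = FALSE)
  }
  scalp <- sprintf("ch%02d", seq_len(n_channels))
  if (anyDuplicated(c(scalp, "EOG1", "EOG2"))) {
    stop("invalid config: duplicate channel labels", call. = FALSE)
  }
  posterior_channels <- as.character(posterior_channels)
  if (length(posterior_channels) < 1 || !all(posterior_channels %in% scalp)) {
    stop("invalid config: posterior_channels must be a non-empty subset of scalp labels",
         call. = FALSE)
  }
  probs <- c(blink_rate = blink_rate, accuracy_means)
  if (any(probs < 0 | probs > 1)) {
    stop("invalid config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(baseline_paf_sd, modulation_sd_f, modulation_sd_m,
           accuracy_logit_sd, rt_sd, paf_trial_sd)
  if (any(sds < 0)) stop("invalid config: SDs must be >= 0", call. = FALSE)
  if (abs(paf_accuracy_r_male_relative) > 1) {
    stop("invalid config: correlation must lie in [-1, 1]", call. = FALSE)
  }
  # generated content tops out around 14 Hz alpha + filtered broadband
  if (sampling_rate <= 2 * 30) {
    stop("invalid config: sampling_rate must exceed twice the highest generated frequency",
         call. = FALSE)
  }
  tt <- c("2P", "2R", "3P", "3R")
  if (!setequal(names(accuracy_means), tt) || !setequal(names(rt_means), tt)) {
    stop("invalid config: accuracy_means and rt_means need names 2P, 2R, 3P, 3R",
         call. = FALSE)
  }
  cfg <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    sampling_rate = sampling_rate,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_trials = as.integer(n_blocks * trials_per_block),
    scalp_channels = scalp,
    eog_channels = c("EOG1", "EOG2"),
    posterior_channels = posterior_channels,
    baseline_paf_mean = baseline_paf_mean, baseline_paf_sd = baseline_paf_sd,
    modulation_mean_f = modulation_mean_f, modulation_sd_f = modulation_sd_f,
    modulation_mean_m = modulation_mean_m, modulation_sd_m = modulation_sd_m,
    aperiodic_exponent = aperiodic_exponent,
    alpha_amplitude = alpha_amplitude, noise_amplitude = noise_amplitude,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    paf_accuracy_r_male_relative = paf_accuracy_r_male_relative,
    accuracy_means = accuracy_means[tt], rt_means = rt_means[tt],
    accuracy_logit_sd = accuracy_logit_sd, rt_sd = rt_sd,
    paf_trial_sd = paf_trial_sd,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  subjects: %d F / %d M; trials: %d blocks x %d = %d\n",
              x$n_females, x$n_males, x$n_blocks, x$trials_per_block,
              x$n_trials))
  cat(sprintf("  montage: %d scalp + 2 EOG channels (%d posterior) @ %g Hz\n",
              length(x$scalp_channels), length(x$posterior_channels),
              x$sampling_rate))
  cat(sprintf("  PAF: baseline %g (SD %g) Hz; modulation F %+.2f (SD %g) / M %+.2f (SD %g) Hz\n",
              x$baseline_paf_mean, x$baseline_paf_sd,
              x$modulation_mean_f, x$modulation_sd_f,
              x$modulation_mean_m, x$modulation_sd_m))
  invisible(x)
}

#' Trial timeline of the working-memory task
#'
#' Every trial follows the same event sequence, with time zero at cue +
#' sample onset: 500 ms fixation baseline, 500 ms cue and sample stimuli,
#' a 2,000 ms memory delay, then test stimuli and response from 2.5 s.
#' Analysis epochs span `[-2.0, 5.5)` s (7.5 s), so consecutive epochs of a
#' continuous session overlap by 2 s. The baseline analysis window is the
#' last 500 ms of fixation, `[-0.5, 0)`; the maintenance window is the last
#' 1,500 ms of the delay, `[1.0, 2.5)`.
#'
#' @return A list with onsets and durations in seconds.
#' @export
trial_timeline <- function() {
  list(
    baseline_onset = -0.5,
    cue_sample_onset = 0,
    sample_duration = 0.5,
    delay_duration = 2.0,
    delay_onset = 0.5,
    test_onset = 2.5,
    response_end = 4.0,
    segment_span = c(-2.0, 5.5),
    trial_spacing = 5.5
  )
}

#' Analysis windows for PAF extraction
#'
#' Half-open time windows (seconds relative to cue onset) over which
#' weighted alpha power is averaged before taking the peak: `baseline`
#' (last 500 ms of fixation), `maintenance` (last 1,500 ms of the memory
#' delay), and `pretest` (baseline onset through delay end, covering both).
#'
#' @return Named list of `c(start, end)` pairs.
#' @export
analysis_windows <- function() {
  list(
    baseline = c(-0.5, 0),
    maintenance = c(1.0, 2.5),
    pretest = c(-0.5, 2.5)
  )
}

task_types <- function() c("2P", "2R", "3P", "3R")
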